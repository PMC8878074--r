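# Minimal reverse-mode differentiation tape.
#
# Nodes are environments holding `value` (numeric array/matrix), `grad`
# (accumulated cotangent, NULL until backward reaches the node), `parents`
# (list of nodes) and `bwd` (function mapping the node's grad to a list of
# parent grads, aligned with `parents`). Values are computed eagerly; the
# graph is only kept so gradients can be propagated. Constants are plain
# arrays, not nodes, and receive no gradient.

ag_node <- function(value, parents = list(), bwd = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$bwd <- bwd
  class(e) <- "ag_node"
  e
}

ag_param <- function(value) ag_node(value)

is_node <- function(x) inherits(x, "ag_node")

ag_value <- function(x) if (is_node(x)) x$value else x

ag_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(node)
}

# Reverse traversal in topological order (iterative DFS; graphs here have a
# few hundred nodes).
ag_backward <- function(root, seed) {
  order <- list()
  seen <- new.env(parent = emptyenv())
  key <- function(n) format.default(n)  # environment identity string
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    n <- top$node
    k <- key(n)
    if (top$stage == 1L) {
      if (!is.null(seen[[k]])) next
      seen[[k]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = n, stage = 2L)
      for (p in n$parents) {
        if (is_node(p) && is.null(seen[[key(p)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      order[[length(order) + 1L]] <- n
    }
  }
  for (n in order) n$grad <- NULL
  root$grad <- seed
  for (i in rev(seq_along(order))) {
    n <- order[[i]]
    if (is.null(n$grad) || is.null(n$bwd)) next
    gs <- n$bwd(n$grad)
    for (j in seq_along(n$parents)) {
      p <- n$parents[[j]]
      if (is_node(p) && !is.null(gs[[j]])) ag_accum(p, gs[[j]])
    }
    if (length(n$parents) > 0L) n$grad <- NULL  # free intermediate cotangents
  }
  invisible(root)
}

# ---- differentiable ops ----------------------------------------------------

ag_conv2d <- function(x, w, b, dilation = 1L) {
  y <- cpp_conv2d_fwd(x$value, w$value, b$value, dilation)
  ag_node(y, list(x, w, b), function(g) {
    r <- cpp_conv2d_bwd(x$value, w$value, g, dilation)
    list(r$gx, r$gw, r$gb)
  })
}

ag_convt2d <- function(x, w, b) {
  y <- cpp_convt2d_fwd(x$value, w$value, b$value)
  ag_node(y, list(x, w, b), function(g) {
    r <- cpp_convt2d_bwd(x$value, w$value, g)
    list(r$gx, r$gw, r$gb)
  })
}

ag_blurdown <- function(x, kernel, stride = 2L) {
  d <- dim(x$value)
  y <- cpp_blurdown_fwd(x$value, unclass(kernel), stride)
  ag_node(y, list(x), function(g) {
    list(cpp_blurdown_bwd(g, unclass(kernel), stride, d[3], d[4]))
  })
}

ag_maxdense <- function(x) {
  r <- cpp_maxdense_fwd(x$value)
  ag_node(r$y, list(x), function(g) list(cpp_maxdense_bwd(g, r$arg)))
}

ag_adaptavg <- function(x, ho, wo) {
  d <- dim(x$value)
  y <- cpp_adaptavg_fwd(x$value, ho, wo)
  ag_node(y, list(x), function(g) list(cpp_adaptavg_bwd(g, d[3], d[4])))
}

ag_resize_nn <- function(x, ho, wo) {
  d <- dim(x$value)
  y <- cpp_resize_nn_fwd(x$value, ho, wo)
  ag_node(y, list(x), function(g) list(cpp_resize_nn_bwd(g, d[3], d[4])))
}

ag_chanmean <- function(x) {
  C <- dim(x$value)[2]
  y <- cpp_chanmean_fwd(x$value)
  ag_node(y, list(x), function(g) list(cpp_chanmean_bwd(g, C)))
}

ag_chanmax <- function(x) {
  C <- dim(x$value)[2]
  r <- cpp_chanmax_fwd(x$value)
  ag_node(r$y, list(x), function(g) list(cpp_chanmax_bwd(g, r$arg, C)))
}

ag_relu <- function(x) {
  mask <- x$value > 0
  y <- x$value
  y[!mask] <- 0
  ag_node(y, list(x), function(g) { g[!mask] <- 0; list(g) })
}

ag_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-x$value))
  ag_node(y, list(x), function(g) list(g * y * (1 - y)))
}

ag_add <- function(x, y) {
  ag_node(x$value + y$value, list(x, y), function(g) list(g, g))
}

# channel-wise scaling: a is an (N, C) matrix of weights
ag_mul_chan <- function(x, a) {
  d <- dim(x$value)
  av <- as.vector(a$value)  # recycles over (h, w) in column-major order
  y <- x$value * av
  ag_node(y, list(x, a), function(g) {
    ga <- matrix(rowSums(matrix(g * x$value, nrow = d[1] * d[2])), d[1], d[2])
    list(g * av, ga)
  })
}

# spatial scaling: s has dim (N, 1, H, W)
ag_mul_spat <- function(x, s) {
  d <- dim(x$value)
  sx <- s$value[, rep(1L, d[2]), , , drop = FALSE]
  y <- x$value * sx
  ag_node(y, list(x, s), function(g) {
    gs <- cpp_chanmean_fwd(g * x$value) * d[2]  # channel sum
    list(g * sx, gs)
  })
}

ag_concat <- function(xs) {
  ds <- lapply(xs, function(x) dim(x$value))
  cs <- vapply(ds, `[`, integer(1), 2L)
  d1 <- ds[[1]]
  y <- array(0, dim = c(d1[1], sum(cs), d1[3], d1[4]))
  at <- 0L
  for (i in seq_along(xs)) {
    y[, at + seq_len(cs[i]), , ] <- xs[[i]]$value
    at <- at + cs[i]
  }
  ag_node(y, xs, function(g) {
    out <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- g[, at + seq_len(cs[i]), , , drop = FALSE]
      at <- at + cs[i]
    }
    out
  })
}

# global average pool -> (N, C) matrix
ag_gap <- function(x) {
  d <- dim(x$value)
  y <- matrix(rowMeans(matrix(x$value, nrow = d[1] * d[2])), d[1], d[2])
  ag_node(y, list(x), function(g) {
    list(array(as.vector(g) / (d[3] * d[4]), dim = d))
  })
}

# squeeze a (N, C, 1, 1) map to an (N, C) matrix
ag_squeeze2 <- function(x) {
  d <- dim(x$value)
  y <- matrix(x$value, d[1], d[2])
  ag_node(y, list(x), function(g) list(array(g, dim = d)))
}

# dense layer on (N, C) matrices
ag_linear <- function(x, w, b) {
  y <- x$value %*% w$value
  y <- sweep(y, 2L, b$value, "+")
  ag_node(y, list(x, w, b), function(g) {
    list(g %*% t(w$value), t(x$value) %*% g, colSums(g))
  })
}

ag_relu_mat <- function(x) {
  mask <- x$value > 0
  y <- x$value
  y[!mask] <- 0
  ag_node(y, list(x), function(g) { g[!mask] <- 0; list(g) })
}

ag_sigmoid_mat <- ag_sigmoid

# wrap a nested list of parameter arrays into nodes (same structure)
params_to_nodes <- function(params) {
  rapply(params, ag_param, classes = c("numeric", "matrix", "array", "integer"),
         how = "replace")
}

# collect gradients from a nested node structure, zeros where unvisited
nodes_to_grads <- function(nodes) {
  rapply(nodes, function(n) {
    if (is.null(n$grad)) {
      g <- n$value
      g[] <- 0
      g
    } else n$grad
  }, classes = "ag_node", how = "replace")
}
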