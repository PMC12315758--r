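# Minimal reverse-mode automatic differentiation tape.
#
# Values are plain R arrays of dim c(H, W, C).  A node is an environment
# holding the value (`v`), the accumulated gradient (`g`), and a backward
# closure (`bk`) that pushes the node's gradient into its parents.  Ops
# append nodes to a tape in creation order; backward() walks the tape in
# reverse.  Parameters are leaf nodes that live in the model, off-tape,
# and keep their gradients across the backward sweep until zeroed.

.tg <- new.env(parent = emptyenv())
.tg$on <- FALSE
.tg$nodes <- list()
.tg$n <- 0L

tg_recording <- function() .tg$on

tg_start <- function() {
  .tg$on <- TRUE
  .tg$nodes <- vector("list", 512L)
  .tg$n <- 0L
  invisible(NULL)
}

tg_stop <- function() {
  .tg$on <- FALSE
  .tg$nodes <- list()
  .tg$n <- 0L
  invisible(NULL)
}

tg_push <- function(node) {
  if (!.tg$on) return(invisible(node))
  n <- .tg$n + 1L
  if (n > length(.tg$nodes)) .tg$nodes <- c(.tg$nodes, vector("list", length(.tg$nodes)))
  .tg$nodes[[n]] <- node
  .tg$n <- n
  invisible(node)
}

new_node <- function(v, bk = NULL, leaf = FALSE) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$g <- NULL
  e$bk <- bk
  class(e) <- "tg_node"
  if (!leaf) tg_push(e)
  e
}

#' @keywords internal
tg_param <- function(v) new_node(v, leaf = TRUE)

is_node <- function(x) inherits(x, "tg_node")
nval <- function(x) if (is_node(x)) x$v else x

accum_grad <- function(node, g) {
  if (is.null(node$g)) node$g <- g else node$g <- node$g + g
  invisible(NULL)
}

# Run backward from a scalar loss node over the current tape.
tg_backward <- function(loss) {
  stopifnot(is_node(loss), length(loss$v) == 1L)
  loss$g <- 1
  if (.tg$n > 0L) {
    for (i in rev(seq_len(.tg$n))) {
      nd <- .tg$nodes[[i]]
      if (!is.null(nd$g) && !is.null(nd$bk)) nd$bk(nd$g)
    }
  }
  invisible(NULL)
}

as_cube <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

# ---- differentiable ops ---------------------------------------------------

t_conv2d <- function(x, w, b, k = 3L, pad = 1L) {
  xv <- as_cube(nval(x))
  y <- cpp_conv2d(xv, w$v, as.numeric(b$v), k, pad)
  if (!.tg$on) return(new_node(y, leaf = TRUE))
  node <- new_node(y)
  node$bk <- function(g) {
    gr <- cpp_conv2d_bwd(xv, w$v, g, k, pad)
    accum_grad(w, gr$gW)
    accum_grad(b, as.numeric(gr$gb))
    if (is_node(x)) accum_grad(x, gr$gx)
  }
  node
}

# PReLU with one learnable slope per channel (slope vector node `a`).
t_prelu <- function(x, a) {
  xv <- nval(x)
  C <- dim(xv)[3]
  av <- rep(as.numeric(a$v), each = prod(dim(xv)[1:2]))
  pos <- xv > 0
  y <- ifelse(pos, xv, av * xv)
  dim(y) <- dim(xv)
  if (!.tg$on) return(new_node(y, leaf = TRUE))
  node <- new_node(y)
  node$bk <- function(g) {
    gx <- ifelse(pos, g, av * g)
    dim(gx) <- dim(xv)
    ga <- .colSums(ifelse(pos, 0, g * xv), prod(dim(xv)[1:2]), C)
    accum_grad(a, ga)
    if (is_node(x)) accum_grad(x, gx)
  }
  node
}

t_relu <- function(x) {
  xv <- nval(x)
  pos <- xv > 0
  y <- xv * pos
  if (!.tg$on) return(new_node(y, leaf = TRUE))
  node <- new_node(y)
  node$bk <- function(g) if (is_node(x)) accum_grad(x, g * pos)
  node
}

# Elementwise maximum of two stacks (ties resolve to the first argument).
t_maxout2 <- function(a, b) {
  av <- nval(a); bv <- nval(b)
  stopifnot(identical(dim(av), dim(bv)))
  take_a <- av >= bv
  y <- ifelse(take_a, av, bv)
  dim(y) <- dim(av)
  if (!.tg$on) return(new_node(y, leaf = TRUE))
  node <- new_node(y)
  node$bk <- function(g) {
    if (is_node(a)) accum_grad(a, g * take_a)
    if (is_node(b)) accum_grad(b, g * (!take_a))
  }
  node
}

t_maxout_all <- function(xs) Reduce(t_maxout2, xs)

t_maxpool2 <- function(x) {
  xv <- as_cube(nval(x))
  r <- cpp_maxpool2(xv)
  H <- dim(xv)[1]; W <- dim(xv)[2]
  if (!.tg$on) {
    node <- new_node(r$y, leaf = TRUE)
  } else {
    node <- new_node(r$y)
    node$bk <- function(g) if (is_node(x)) accum_grad(x, cpp_maxpool2_bwd(g, r$idx, H, W))
  }
  node$idx <- r$idx
  node$in_hw <- c(H, W)
  node
}

t_maxunpool2 <- function(x, idx, H, W) {
  xv <- as_cube(nval(x))
  y <- cpp_maxunpool2(xv, idx, H, W)
  if (!.tg$on) return(new_node(y, leaf = TRUE))
  node <- new_node(y)
  node$bk <- function(g) {
    if (is_node(x)) accum_grad(x, cpp_maxunpool2_bwd(g, idx, dim(xv)[1], dim(xv)[2]))
  }
  node
}

t_resize_bilinear <- function(x, oh, ow) {
  xv <- as_cube(nval(x))
  if (oh == dim(xv)[1] && ow == dim(xv)[2]) {
    if (is_node(x)) return(x)
    return(new_node(xv, leaf = TRUE))
  }
  y <- cpp_resize_bilinear(xv, oh, ow)
  if (!.tg$on) return(new_node(y, leaf = TRUE))
  node <- new_node(y)
  node$bk <- function(g) {
    if (is_node(x)) accum_grad(x, cpp_resize_bilinear_bwd(g, dim(xv)[1], dim(xv)[2]))
  }
  node
}

# Zero-pad at the bottom/right to (H, W); crop is its inverse.
t_pad_to <- function(x, H, W) {
  xv <- as_cube(nval(x))
  h <- dim(xv)[1]; w <- dim(xv)[2]; C <- dim(xv)[3]
  if (h == H && w == W) return(if (is_node(x)) x else new_node(xv, leaf = TRUE))
  y <- array(0, c(H, W, C))
  y[seq_len(h), seq_len(w), ] <- xv
  if (!.tg$on) return(new_node(y, leaf = TRUE))
  node <- new_node(y)
  node$bk <- function(g) {
    if (is_node(x)) accum_grad(x, g[seq_len(h), seq_len(w), , drop = FALSE])
  }
  node
}

t_crop_to <- function(x, H, W) {
  xv <- as_cube(nval(x))
  h <- dim(xv)[1]; w <- dim(xv)[2]; C <- dim(xv)[3]
  if (h == H && w == W) return(if (is_node(x)) x else new_node(xv, leaf = TRUE))
  y <- xv[seq_len(H), seq_len(W), , drop = FALSE]
  if (!.tg$on) return(new_node(y, leaf = TRUE))
  node <- new_node(y)
  node$bk <- function(g) {
    gx <- array(0, c(h, w, C))
    gx[seq_len(H), seq_len(W), ] <- g
    if (is_node(x)) accum_grad(x, gx)
  }
  node
}

t_concat_c <- function(xs) {
  vs <- lapply(xs, function(x) as_cube(nval(x)))
  cs <- vapply(vs, function(v) dim(v)[3], 0L)
  y <- array(0, c(dim(vs[[1]])[1:2], sum(cs)))
  at <- 0L
  for (v in vs) {
    y[, , at + seq_len(dim(v)[3])] <- v
    at <- at + dim(v)[3]
  }
  if (!.tg$on) return(new_node(y, leaf = TRUE))
  node <- new_node(y)
  node$bk <- function(g) {
    at <- 0L
    for (i in seq_along(xs)) {
      if (is_node(xs[[i]])) accum_grad(xs[[i]], g[, , at + seq_len(cs[i]), drop = FALSE])
      at <- at + cs[i]
    }
  }
  node
}

t_sub <- function(a, b) {
  y <- nval(a) - nval(b)
  if (!.tg$on) return(new_node(y, leaf = TRUE))
  node <- new_node(y)
  node$bk <- function(g) {
    if (is_node(a)) accum_grad(a, g)
    if (is_node(b)) accum_grad(b, -g)
  }
  node
}

# Per-channel batch normalization over the spatial axes of one stack.
# Statistics are taken from the current stack while training; running
# moments are tracked in the `state` environment and used in eval mode.
t_batchnorm <- function(x, gamma, beta, state, training, momentum = 0.1, eps = 1e-5) {
  xv <- as_cube(nval(x))
  d <- dim(xv); n <- prod(d[1:2]); C <- d[3]
  xm <- matrix(xv, n, C)
  if (training) {
    mu <- .colMeans(xm, n, C)
    va <- .colMeans(xm^2, n, C) - mu^2
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va * n / max(1, n - 1)
  } else {
    mu <- state$mean
    va <- state$var
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(xm, 2L, mu, "-") * rep(inv, each = n)
  y <- sweep(xhat, 2L, as.numeric(gamma$v), "*")
  y <- sweep(y, 2L, as.numeric(beta$v), "+")
  dim(y) <- d
  if (!.tg$on) return(new_node(y, leaf = TRUE))
  node <- new_node(y)
  node$bk <- function(g) {
    gm <- matrix(g, n, C)
    accum_grad(gamma, .colSums(gm * xhat, n, C))
    accum_grad(beta, .colSums(gm, n, C))
    gxhat <- sweep(gm, 2L, as.numeric(gamma$v), "*")
    if (training) {
      s1 <- .colMeans(gxhat, n, C)
      s2 <- .colMeans(gxhat * xhat, n, C)
      gx <- (gxhat - rep(s1, each = n) - xhat * rep(s2, each = n)) * rep(inv, each = n)
    } else {
      gx <- gxhat * rep(inv, each = n)
    }
    dim(gx) <- d
    if (is_node(x)) accum_grad(x, gx)
  }
  node
}

# lambda-weighted candidate combination: Y = sum(l_i Y_i) / sum(l_i).
t_combine <- function(cands, lambdas) {
  lv <- as.numeric(lambdas$v)
  L <- sum(lv)
  if (abs(L) < 1e-12) stop("degenerate candidate combination: sum(lambda) is zero")
  vs <- lapply(cands, nval)
  y <- Reduce(`+`, Map(function(v, l) v * l, vs, lv)) / L
  if (!.tg$on) return(new_node(y, leaf = TRUE))
  node <- new_node(y)
  node$bk <- function(g) {
    gl <- vapply(vs, function(v) sum(g * (v - y)) / L, 0)
    accum_grad(lambdas, gl)
    for (i in seq_along(cands)) {
      if (is_node(cands[[i]])) accum_grad(cands[[i]], g * (lv[i] / L))
    }
  }
  node
}

t_mean_abs <- function(x, target) {
  d <- nval(x) - target
  y <- mean(abs(d))
  if (!.tg$on) return(new_node(y, leaf = TRUE))
  node <- new_node(y)
  node$bk <- function(g) {
    if (is_node(x)) accum_grad(x, g * sign(d) / length(d))
  }
  node
}

t_mean_sq <- function(x, target) {
  d <- nval(x) - target
  y <- mean(d^2)
  if (!.tg$on) return(new_node(y, leaf = TRUE))
  node <- new_node(y)
  node$bk <- function(g) {
    if (is_node(x)) accum_grad(x, g * 2 * d / length(d))
  }
  node
}

t_add_scalar_node <- function(a, b) {
  y <- nval(a) + nval(b)
  if (!.tg$on) return(new_node(y, leaf = TRUE))
  node <- new_node(y)
  node$bk <- function(g) {
    if (is_node(a)) accum_grad(a, g)
    if (is_node(b)) accum_grad(b, g)
  }
  node
}

# Emulated reduced-precision rounding (value-only; gradients untouched).
t_round_single <- function(x) {
  node_v <- round_to_single(nval(x))
  if (!.tg$on) return(new_node(node_v, leaf = TRUE))
  node <- new_node(node_v)
  node$bk <- function(g) if (is_node(x)) accum_grad(x, g)
  node
}

round_to_single <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
               n = length(x), size = 4L)
  dim(y) <- d
  y
}
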