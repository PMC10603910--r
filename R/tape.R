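# Minimal reverse-mode automatic differentiation.
#
# A "tape" records operation nodes in execution order; backward() replays the
# tape in reverse, calling each node's vector-Jacobian product. Nodes are
# environments so gradients can be accumulated in place. Layer functions in
# layers.R accept either a node (training, tape active) or a bare array
# (inference); `.val()` unwraps both.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$n <- 0L
  tp
}

tape_node <- function(tape, value, parents = list(), vjp = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$vjp <- vjp
  nd$name <- NULL
  tape$n <- tape$n + 1L
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

# leaf node for a learnable parameter; `name` keys the gradient dictionary
tape_param <- function(tape, value, name) {
  nd <- tape_node(tape, value)
  nd$name <- name
  nd
}

is_node <- function(x) is.environment(x)

.val <- function(x) if (is.environment(x)) x$value else x

accumulate_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

# Reverse sweep from `root` (a scalar-valued node). Returns a named list of
# gradients for all parameter leaves that received one.
tape_backward <- function(tape, root, seed_grad = 1) {
  root$grad <- seed_grad
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$vjp)) next
    gs <- nd$vjp(nd$grad)
    for (j in seq_along(nd$parents)) {
      # parents may be plain arrays (constants); only nodes accumulate
      if (!is.null(gs[[j]]) && is.environment(nd$parents[[j]]))
        accumulate_grad(nd$parents[[j]], gs[[j]])
    }
  }
  grads <- list()
  for (i in seq_len(tape$n)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$name) && !is.null(nd$grad)) grads[[nd$name]] <- nd$grad
  }
  grads
}
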