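# Minimal reverse-mode autodifferentiation on a linear tape.
#
# Feature maps are stored as dense (B*H*W) x C matrices, rows ordered with the
# image row index fastest, then column, then batch element, so that
# matrix(aperm-free) reshapes of H x W x C arrays are free. Every node carries
# its logical dimensions c(B, H, W, C); reductions (global pooling, losses)
# carry dim = NULL.

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 64L)
  t$n <- 0L
  t$pids <- list() # parameter name -> node id
  t
}

ag_node <- function(tape, val, dim = NULL, parents = integer(), bw = NULL) {
  id <- tape$n + 1L
  if (id > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[id]] <- list(val = val, dim = dim, parents = parents, bw = bw)
  tape$n <- id
  list(id = id, dim = dim)
}

ag_val <- function(tape, h) {
  id <- h$id # force the handle before touching the node list: creating a
  # node (e.g. a lazily-built parameter) may grow tape$nodes
  tape$nodes[[id]]$val
}

ag_input <- function(tape, val, dim) ag_node(tape, val, dim)

# Parameters are identified by name; repeated use within one tape reuses the
# same node so gradients accumulate across shared weights.
ag_param <- function(tape, name, val) {
  if (!is.null(tape$pids[[name]])) return(tape$pids[[name]])
  h <- ag_node(tape, val, dim = NULL)
  tape$pids[[name]] <- h
  h
}

# Backpropagate from a scalar node; returns list(param = named list of grads).
ag_backward <- function(tape, h) {
  grads <- vector("list", tape$n)
  grads[[h$id]] <- 1
  for (id in seq(tape$n, 1L)) {
    g <- grads[[id]]
    nd <- tape$nodes[[id]]
    if (is.null(g) || is.null(nd$bw)) next
    pg <- nd$bw(g)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[k]
      if (is.null(pg[[k]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  out <- list()
  for (nm in names(tape$pids)) out[[nm]] <- grads[[tape$pids[[nm]]$id]]
  out
}
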