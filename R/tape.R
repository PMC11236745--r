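# Reverse-mode differentiation tape.
#
# All network numerics in this package run through a minimal define-by-run
# tape: every tensor op appends a node with a backward closure, and
# tape_backward() replays the closures in reverse, accumulating gradients.
# Values are plain R arrays in (H, W, C, N) layout; scalars are length-1
# numerics. When `tape` is NULL every op is a pure forward computation
# (inference mode) with no recording overhead.

#' Create an empty differentiation tape
#'
#' @return An environment holding the recorded operations, ready to be
#'   passed to the tensor ops and later to [tape_backward()].
#' @keywords internal
new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$n <- 0L
  tp$ops <- list()        # per node: list(ins = ids, back = closure) or NULL for leaves
  tp$leaf_names <- list() # id -> parameter name for leaves
  tp$leaf_ids <- list()   # parameter name -> id (dedupes shared uses)
  tp$grads <- NULL
  tp
}

# A node is list(id, val). id is NA when untaped.
tp_node <- function(tape, val, ins = integer(), back = NULL) {
  if (is.null(tape)) return(list(id = NA_integer_, val = val))
  tape$n <- tape$n + 1L
  id <- tape$n
  tape$ops[[id]] <- if (is.null(back)) NULL else list(ins = ins, back = back)
  list(id = id, val = val)
}

#' Register a trainable parameter on the tape
#'
#' @param tape a tape from [new_tape()] (or NULL for inference).
#' @param arr parameter value (array).
#' @param name parameter name used to key the gradient.
#' @keywords internal
tp_leaf <- function(tape, arr, name) {
  if (!is.null(tape)) {
    cached <- tape$leaf_ids[[name]]
    if (!is.null(cached)) return(list(id = cached, val = arr))
  }
  nd <- tp_node(tape, arr)
  if (!is.null(tape)) {
    tape$leaf_names[[nd$id]] <- name
    tape$leaf_ids[[name]] <- nd$id
  }
  nd
}

nd_val <- function(x) if (is.list(x) && !is.null(x$val)) x$val else x
nd_id  <- function(x) if (is.list(x) && !is.null(x$id)) x$id else NA_integer_

#' Run backward accumulation from a scalar loss node
#'
#' @param tape the tape the graph was recorded on.
#' @param loss the scalar output node.
#' @return Invisibly, a named list of gradients for every leaf registered
#'   with [tp_leaf()]; also stored in `tape$param_grads`.
#' @keywords internal
tape_backward <- function(tape, loss) {
  grads <- vector("list", tape$n)
  grads[[loss$id]] <- 1
  for (id in seq.int(tape$n, 1L)) {
    op <- tape$ops[[id]]
    g <- grads[[id]]
    if (is.null(op) || is.null(g)) next
    gs <- op$back(g)
    ins <- op$ins
    for (k in seq_along(ins)) {
      i <- ins[k]
      if (is.na(i) || is.null(gs[[k]])) next
      grads[[i]] <- if (is.null(grads[[i]])) gs[[k]] else grads[[i]] + gs[[k]]
    }
    grads[id] <- list(NULL)   # free (keep list length)
  }
  # a shared parameter (one reused block) registers one leaf per use;
  # its gradient is the sum over uses
  pg <- list()
  for (id in seq_len(tape$n)) {
    nm <- if (id <= length(tape$leaf_names)) tape$leaf_names[[id]] else NULL
    if (is.null(nm)) next
    g <- if (is.null(grads[[id]])) 0 else grads[[id]]
    pg[[nm]] <- if (is.null(pg[[nm]])) g else pg[[nm]] + g
  }
  tape$param_grads <- pg
  invisible(pg)
}
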