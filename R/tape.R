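# Minimal reverse-mode gradient tape over R arrays.
#
# Every differentiable quantity is either a plain array/numeric (treated as a
# constant) or a `tp` node holding a value plus its position on a tape. Ops
# that receive only plain inputs return plain values, so the same forward code
# serves both inference (no tape, no overhead) and training.

tape_new <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e$parents <- vector("list", 64L)
  e$backfns <- vector("list", 64L)
  e
}

is_tp <- function(x) inherits(x, "tp")

#' @noRd
tp_leaf <- function(tape, value) tp_node(tape, value, integer(), NULL)

tp_node <- function(tape, value, parents, backfn) {
  tape$n <- tape$n + 1L
  id <- tape$n
  if (id > length(tape$parents)) {          # grow geometrically
    length(tape$parents) <- 2L * id
    length(tape$backfns) <- 2L * id
  }
  tape$parents[[id]] <- parents
  if (!is.null(backfn)) tape$backfns[[id]] <- backfn
  structure(list(id = id, value = value, tape = tape), class = "tp")
}

vof <- function(x) if (is_tp(x)) x$value else x
idof <- function(x) if (is_tp(x)) x$id else 0L

# Record an op: `inputs` is a list possibly mixing tp nodes and constants;
# backfn(grad_out) must return a list of gradients aligned with `inputs`
# (NULL entries for constants are fine).
tp_op <- function(value, inputs, backfn) {
  tracked <- FALSE
  for (x in inputs) if (is_tp(x)) { tracked <- TRUE; tape <- x$tape; break }
  if (!tracked) return(value)
  tp_node(tape, value, vapply(inputs, idof, integer(1)), backfn)
}

# Reverse sweep from a scalar root. Gradients for every node are left on the
# tape; read them back with tp_grad().
tp_backward <- function(root, seed = 1) {
  stopifnot(is_tp(root))
  tape <- root$tape
  grads <- vector("list", tape$n)
  grads[[root$id]] <- seed
  for (id in seq.int(tape$n, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    bf <- tape$backfns[[id]]
    if (is.null(bf)) next
    pg <- bf(g)
    ps <- tape$parents[[id]]
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (p == 0L || is.null(pg[[j]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
  }
  tape$grads <- grads
  invisible(grads)
}

tp_grad <- function(x, zero_ok = TRUE) {
  stopifnot(is_tp(x))
  g <- x$tape$grads[[x$id]]
  if (is.null(g)) {
    if (!zero_ok) stop("no gradient reached this node")
    g <- array(0, dim_of(vof(x)))
  }
  if (is.null(dim(g)) && !is.null(dim(vof(x)))) g <- array(g, dim(vof(x)))
  g
}

dim_of <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# ---- elementwise / reduction ops ------------------------------------------

tp_add <- function(a, b) {
  tp_op(vof(a) + vof(b), list(a, b), function(g) list(g, g))
}

tp_sub <- function(a, b) {
  tp_op(vof(a) - vof(b), list(a, b), function(g) list(g, -g))
}

tp_scale <- function(a, s) {                # s: plain scalar
  tp_op(vof(a) * s, list(a), function(g) list(g * s))
}

tp_mul <- function(a, b) {                  # elementwise, same shape
  av <- vof(a); bv <- vof(b)
  tp_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

tp_mean <- function(a) {
  av <- vof(a); n <- length(av)
  tp_op(mean(av), list(a), function(g) list(array(g / n, dim_of(av))))
}

tp_sum <- function(a) {
  av <- vof(a)
  tp_op(sum(av), list(a), function(g) list(array(g, dim_of(av))))
}

tp_abs <- function(a) {
  av <- vof(a); s <- sign(av)
  tp_op(abs(av), list(a), function(g) list(g * s))
}

tp_log <- function(a) {
  av <- vof(a)
  tp_op(log(av), list(a), function(g) list(g / av))
}

tp_clamp <- function(a, lo, hi) {
  av <- vof(a)
  inside <- (av >= lo) & (av <= hi)
  tp_op(pmin(pmax(av, lo), hi), list(a), function(g) list(g * inside))
}

tp_square_sum <- function(a) {              # sum(a^2), used for L2 penalty
  av <- vof(a)
  tp_op(sum(av * av), list(a), function(g) list(2 * g * av))
}

# ---- activations -----------------------------------------------------------

tp_relu <- function(a) {
  av <- vof(a); m <- av > 0
  tp_op(av * m, list(a), function(g) list(g * m))
}

tp_lrelu <- function(a, slope = 0.2) {
  av <- vof(a)
  sc <- (av > 0) + slope * (av <= 0)
  tp_op(av * sc, list(a), function(g) list(g * sc))
}

tp_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-vof(a)))
  tp_op(y, list(a), function(g) list(g * y * (1 - y)))
}
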