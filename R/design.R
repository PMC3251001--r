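#' Compiled single-precision design matrix
#'
#' Wraps an `N x D` stimulus matrix in a float32 copy held by compiled code,
#' halving the memory traffic of the two matrix-vector products that
#' dominate each optimizer iteration.  Products are accumulated and
#' returned in double precision.
#'
#' @param S numeric `N x D` matrix.
#' @return Object of class `"mid_design"`.
#' @keywords internal
make_design <- function(S) {
  structure(list(ptr = design_build(S), n = nrow(S), d = ncol(S)),
            class = "mid_design")
}

# S %*% v for either a plain matrix or a compiled design
mv <- function(S, v) {
  if (inherits(S, "mid_design")) design_matvec(S$ptr, as.numeric(v))
  else as.vector(S %*% v)
}

# t(S) %*% a
cv <- function(S, a) {
  if (inherits(S, "mid_design")) design_crossvec(S$ptr, as.numeric(a))
  else as.vector(crossprod(S, a))
}

# one stimulus row
drow <- function(S, i) {
  if (inherits(S, "mid_design")) as.numeric(design_row(S$ptr, as.integer(i)))
  else as.vector(S[i, ])
}

dnr <- function(S) if (inherits(S, "mid_design")) S$n else nrow(S)
dnc <- function(S) if (inherits(S, "mid_design")) S$d else ncol(S)

# S %*% M column-wise (M has few columns)
mmat <- function(S, M) {
  M <- as.matrix(M)
  out <- matrix(0, dnr(S), ncol(M))
  for (j in seq_len(ncol(M))) out[, j] <- mv(S, M[, j])
  out
}

# second-moment matrices t(S) S and t(S) diag(w) S
gram <- function(S) {
  if (inherits(S, "mid_design")) design_gram(S$ptr) else crossprod(S)
}
gram_weighted <- function(S, w) {
  if (inherits(S, "mid_design")) design_gram_weighted(S$ptr, as.numeric(w))
  else crossprod(S, S * w)
}
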