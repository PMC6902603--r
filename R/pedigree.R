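#' Validate and topologically order a pedigree
#'
#' A pedigree is a data frame with columns `animal`, `sire`, `dam`; unknown
#' parents are coded `0` (or `NA`). Every named parent must itself appear as
#' an animal, ids must be unique, and no animal may be its own ancestor.
#' Records are reordered so that parents always precede their offspring,
#' which is the order required by the tabular relationship-matrix recursion.
#'
#' @param pedigree data frame with columns `animal`, `sire`, `dam` (extra
#'   columns are carried along).
#' @return A tibble in topological order with an `id_index` attribute giving
#'   the id -> row-index map used by downstream matrices.
#' @examples
#' ped <- tibble::tibble(animal = c(3, 1, 2), sire = c(1, 0, 0), dam = c(2, 0, 0))
#' ped_validate(ped)
#' @export
ped_validate <- function(pedigree) {
  stopifnot(is.data.frame(pedigree))
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(pedigree))) {
    abort("pedigree must have columns 'animal', 'sire', 'dam'")
  }
  ped <- tibble::as_tibble(pedigree)
  ped$sire[is.na(ped$sire)] <- 0
  ped$dam[is.na(ped$dam)] <- 0
  ids <- ped$animal
  if (anyNA(ids)) abort("missing animal id")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate animal id: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  parents <- setdiff(c(ped$sire, ped$dam), 0)
  missing <- setdiff(parents, ids)
  if (length(missing)) {
    abort(paste0("parent id not present as an animal: ",
                 paste(missing, collapse = ", ")))
  }
  # Kahn's algorithm: place animals whose parents are already placed
  q <- nrow(ped)
  pos <- rep(NA_integer_, q)
  placed <- setNames(rep(FALSE, q), as.character(ids))
  sire_ch <- as.character(ped$sire)
  dam_ch <- as.character(ped$dam)
  remaining <- seq_len(q)
  order_idx <- integer(0)
  repeat {
    ready <- remaining[
      (ped$sire[remaining] == 0 | placed[sire_ch[remaining]]) &
      (ped$dam[remaining] == 0 | placed[dam_ch[remaining]])
    ]
    if (!length(ready)) break
    order_idx <- c(order_idx, ready)
    placed[as.character(ids[ready])] <- TRUE
    remaining <- setdiff(remaining, ready)
  }
  if (length(remaining)) {
    abort(paste0("pedigree contains a cycle (an animal is its own ancestor); ",
                 "involved ids: ", paste(ids[remaining], collapse = ", ")))
  }
  out <- ped[order_idx, , drop = FALSE]
  idx <- setNames(seq_len(q), as.character(out$animal))
  attr(out, "id_index") <- idx
  out
}

#' Additive relationship matrix from a pedigree (tabular method)
#'
#' Builds the q x q additive (numerator) relationship matrix A by the tabular
#' recursion in topological order: founders have a_ii = 1 and a_ij = 0 among
#' themselves; for animal i with parents s, d,
#' a_ij = (a_js + a_jd) / 2 for j earlier than i, and
#' a_ii = 1 + a_sd / 2. Unknown parents contribute 0 (founder assumption).
#' The diagonal equals 1 + F_i where F_i is the inbreeding coefficient.
#'
#' @param pedigree data frame accepted by [ped_validate()].
#' @return Symmetric matrix with animal ids as dimnames.
#' @examples
#' ped <- tibble::tibble(animal = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2))
#' build_A(ped)
#' @export
build_A <- function(pedigree) {
  ped <- ped_validate(pedigree)
  q <- nrow(ped)
  idx <- attr(ped, "id_index")
  # parent row-indices in topological order; 0 -> index q+1, a padded zero slot
  si <- ifelse(ped$sire == 0, q + 1L, idx[as.character(ped$sire)])
  di <- ifelse(ped$dam == 0, q + 1L, idx[as.character(ped$dam)])
  A <- matrix(0, q + 1L, q + 1L)
  for (i in seq_len(q)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * (A[j, s] + A[j, d])
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + 0.5 * A[s, d]
  }
  A <- A[seq_len(q), seq_len(q), drop = FALSE]
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

#' Cholesky factor of a relationship matrix
#'
#' Returns the lower-triangular L with L L' = A, used to whiten the genetic
#' effects (a = L u). Errors if A is not positive definite, naming the
#' leading minor that failed.
#'
#' @param A symmetric positive-definite matrix.
#' @param tol relative reconstruction tolerance checked after factorization.
#' @return Lower-triangular matrix L.
#' @export
cholesky_factor <- function(A, tol = 1e-10) {
  R <- tryCatch(chol(A), error = function(e) {
    abort(paste0("relationship matrix is not positive definite: ",
                 conditionMessage(e)))
  })
  L <- t(R)
  err <- max(abs(L %*% t(L) - A)) / max(abs(A))
  if (err > tol) {
    abort(sprintf("Cholesky reconstruction error %.3g exceeds tolerance", err))
  }
  L
}

#' Relationship factor: A, its Cholesky factor and id map
#'
#' Convenience constructor bundling the additive relationship matrix, its
#' lower Cholesky factor and the animal-id ordering, as consumed by the
#' samplers.
#'
#' @param pedigree data frame accepted by [ped_validate()], or a matrix
#'   already built by [build_A()].
#' @return Object of class `relationship_factor`: list with elements `A`,
#'   `L`, `q`, `ids`.
#' @export
relationship_factor <- function(pedigree) {
  sire_idx <- dam_idx <- dsqrt <- NULL
  if (is.matrix(pedigree)) {
    A <- pedigree
    ids <- rownames(A)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(A)))
  } else {
    ped <- ped_validate(pedigree)
    A <- build_A(ped)
    ids <- rownames(A)
    idx <- attr(ped, "id_index")
    q <- nrow(ped)
    sire_idx <- ifelse(ped$sire == 0, 0L,
                       unname(idx[as.character(ped$sire)]))
    dam_idx <- ifelse(ped$dam == 0, 0L,
                      unname(idx[as.character(ped$dam)]))
    # Mendelian-sampling variances of A = T D T' (L = T sqrt(D)):
    # d_i = a_ii - (a_ss + a_dd)/4 - a_sd/2, unknown-parent terms zero
    Ap <- rbind(cbind(A, 0), 0)             # padded zero row/col for unknowns
    s <- ifelse(sire_idx == 0L, q + 1L, sire_idx)
    d <- ifelse(dam_idx == 0L, q + 1L, dam_idx)
    dvec <- diag(A) - 0.25 * (Ap[cbind(s, s)] + Ap[cbind(d, d)]) -
      0.5 * Ap[cbind(s, d)]
    dsqrt <- sqrt(dvec)
  }
  L <- cholesky_factor(A)
  structure(list(A = A, L = L, q = nrow(A), ids = ids,
                 sire = sire_idx, dam = dam_idx, dsqrt = dsqrt),
            class = "relationship_factor")
}

#' @export
print.relationship_factor <- function(x, ...) {
  cat("<relationship_factor>", x$q, "animals; mean inbreeding",
      sprintf("%.4f", mean(diag(x$A) - 1)), "\n")
  invisible(x)
}

as_rel_factor <- function(pedigree) {
  if (inherits(pedigree, "relationship_factor")) return(pedigree)
  relationship_factor(pedigree)
}

#' Inbreeding coefficients from a pedigree
#'
#' @param pedigree data frame accepted by [ped_validate()] or a
#'   `relationship_factor`.
#' @return Tibble with columns `animal` and `F` (diagonal of A minus 1).
#' @export
inbreeding <- function(pedigree) {
  rf <- as_rel_factor(pedigree)
  tibble::tibble(animal = rf$ids, F = diag(rf$A) - 1)
}
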