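#' Representational dissimilarity matrix (1 - Pearson r)
#'
#' Pairwise correlation distance between condition-averaged multivoxel
#' patterns, in the mandated block order (body, face, voice session 1, voice
#' session 2; anger, happy, neutral, fear within each block). Entries lie in
#' \[0, 2\] with a zero diagonal; rows with zero variance give undefined
#' entries, which are flagged rather than silently dropped.
#'
#' @param patterns conditions x voxels matrix (rows in the mandated order, as
#'   from [condition_patterns()]).
#' @return an `rdm` matrix (conditions x conditions) with a `condition_order`
#'   attribute.
#' @export
compute_rdm <- function(patterns) {
  if (ncol(patterns) < 2) stop("RDMs need at least 2 voxels", call. = FALSE)
  sds <- apply(patterns, 1, stats::sd)
  if (any(!is.na(sds) & sds == 0)) {
    warning("zero-variance pattern(s); corresponding RDM entries are NA: ",
            paste(rownames(patterns)[!is.na(sds) & sds == 0], collapse = ", "))
  }
  suppressWarnings(R <- stats::cor(t(patterns)))
  D <- 1 - R
  diag(D)[!is.na(diag(D))] <- 0
  structure(D, class = c("rdm", "matrix"),
            condition_order = rownames(patterns))
}

#' Average RDMs across subjects for display
#'
#' @param rdms list of `rdm` matrices with identical condition order.
#' @return the element-wise mean `rdm`.
#' @export
average_rdm <- function(rdms) {
  out <- Reduce(`+`, lapply(rdms, unclass)) / length(rdms)
  structure(out, class = c("rdm", "matrix"),
            condition_order = attr(rdms[[1]], "condition_order"))
}

#' Within- versus between-modality-block dissimilarity
#'
#' Summarises an RDM's modality structure: mean off-diagonal dissimilarity for
#' condition pairs inside the same stimulus-type/session block versus pairs
#' spanning two blocks. A strong modality code shows between > within.
#'
#' @param rdm an `rdm`.
#' @return named numeric: `within`, `between`.
#' @export
rdm_block_contrast <- function(rdm) {
  cond <- attr(rdm, "condition_order")
  block <- sub("_[a-z]+$", "", cond)
  same <- outer(block, block, "==")
  off <- !diag(TRUE, length(cond))
  c(within = mean(rdm[same & off], na.rm = TRUE),
    between = mean(rdm[!same], na.rm = TRUE))
}
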