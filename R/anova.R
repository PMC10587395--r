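#' Voxel-wise repeated-measures ANOVA on condition betas
#'
#' For each voxel, averages every subject's condition betas within the levels
#' of the chosen factor (stimulus category: face / body / voice, or emotion:
#' anger / happy / neutral / fear) and runs a one-way repeated-measures ANOVA
#' across subjects (subjects as the blocking factor). Computed in closed form,
#' vectorised over voxels:
#' F = MS(factor) / MS(factor x subject), df = (L - 1), (L - 1)(S - 1).
#'
#' @param condition_betas list of per-subject `condition_beta_set`s with
#'   identical condition ordering and voxel grids.
#' @param factor `"modality"` (stimulus category) or `"emotion"`.
#' @return list with per-voxel `F`, one-sided `p`, and the degrees of freedom.
#'   P-values are left uncorrected; apply [bh_fdr()] or [fwe_correct()]
#'   downstream.
#' @export
anova_factor_map <- function(condition_betas, factor = c("modality", "emotion")) {
  factor <- match.arg(factor)
  S <- length(condition_betas)
  if (S < 2) stop("at least 2 subjects are required", call. = FALSE)
  labels <- condition_betas[[1]]$labels
  lev <- if (factor == "modality") labels$stimulus_type else labels$emotion
  levels <- unique(lev)
  L <- length(levels)
  if (L < 2) stop("factor has a single level", call. = FALSE)
  V <- ncol(condition_betas[[1]]$betas)
  # subject x level means, stacked as (S * L) x V
  M <- array(0, c(S, L, V))
  for (s in seq_len(S)) {
    b <- condition_betas[[s]]$betas
    stopifnot(ncol(b) == V)
    for (l in seq_len(L)) {
      M[s, l, ] <- colMeans(b[lev == levels[l], , drop = FALSE])
    }
  }
  grand <- apply(M, 3, mean)
  lev_means <- apply(M, c(2, 3), mean)     # L x V
  sub_means <- apply(M, c(1, 3), mean)     # S x V
  ss_factor <- S * colSums((lev_means - matrix(grand, L, V, byrow = TRUE))^2)
  ss_subj <- L * colSums((sub_means - matrix(grand, S, V, byrow = TRUE))^2)
  ss_total <- apply(M, 3, function(x) sum((x - mean(x))^2))
  ss_err <- pmax(ss_total - ss_factor - ss_subj, 0)
  df1 <- L - 1
  df2 <- (L - 1) * (S - 1)
  Fv <- (ss_factor / df1) / (ss_err / df2)
  Fv[ss_factor == 0 & ss_err == 0] <- 0
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  p[Fv == 0] <- 1
  list(F = Fv, p = p, df = c(df1, df2), factor = factor, levels = levels)
}
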