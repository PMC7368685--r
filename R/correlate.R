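# Pearson correlation of substitution-rate measures against gene
# characteristics, in the 12-panel layout: {dN, dS, omega} against each of
# GD, pi, PV and PI.

sig_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Pearson correlation with a two-sided t test
#'
#' r is the sample Pearson correlation, t = r sqrt((n-2)/(1-r^2)), and the
#' two-sided p-value comes from the Student t distribution with n - 2 degrees
#' of freedom. Observations with a missing value in either variable are
#' removed pairwise.
#'
#' @param x,y Numeric vectors of equal length.
#' @param x_name,y_name Labels for the output record.
#' @return One-row data frame (`x`, `y`, `n`, `r`, `t`, `df`, `p`, `stars`).
#' @export
pearson_test <- function(x, y, x_name = deparse(substitute(x)),
                         y_name = deparse(substitute(y))) {
  force(x_name)
  force(y_name)
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need n >= 3 complete pairs, got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: Pearson correlation undefined")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  df <- n - 2L
  t_stat <- if (abs(r) == 1) sign(r) * Inf else r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(abs(t_stat), df = df, lower.tail = FALSE)
  data.frame(x = x_name, y = y_name, n = n, r = r, t = t_stat, df = df,
             p = p, stars = sig_stars(p), stringsAsFactors = FALSE)
}

#' The 12-panel rate-versus-characteristic correlation report
#'
#' Correlates each substitution-rate measure (dN, dS, omega) with gene-tree
#' discordance (GD), nucleotide diversity (pi), percent variability (PV) and
#' phylogenetic informativeness (PI_max), in panel order a-l: GD row first,
#' then pi, PV and PI, each against dN, dS, omega. Genes missing either
#' variable are excluded pairwise, so n varies per panel.
#'
#' @param profiles Data frame of per-gene profiles carrying columns `dN`,
#'   `dS`, `omega`, `GD`, `pi`, `PV`, `PI_max`.
#' @param holm Apply a Holm correction across the 12 panels (adds `p_adj`)?
#' @return Data frame of 12 correlation records with a `panel` column.
#' @export
rates_vs_characteristics <- function(profiles, holm = FALSE) {
  rate_cols <- c("dN", "dS", "omega")
  char_cols <- c(GD = "GD", pi = "pi", PV = "PV", PI = "PI_max")
  missing_cols <- setdiff(c(rate_cols, unname(char_cols)), names(profiles))
  if (length(missing_cols))
    stop("profile table lacks column(s): ", paste(missing_cols, collapse = ", "))
  out <- list()
  panel <- letters[1:12]
  k <- 0L
  for (ch in seq_along(char_cols)) for (rc in rate_cols) {
    k <- k + 1L
    xv <- profiles[[rc]]
    yv <- profiles[[char_cols[ch]]]
    rec <- tryCatch(
      pearson_test(xv, yv, x_name = rc, y_name = names(char_cols)[ch]),
      error = function(e) {
        # degenerate panel (constant variable or too few complete pairs):
        # keep the 12-row layout with a missing record
        data.frame(x = rc, y = names(char_cols)[ch],
                   n = sum(!is.na(xv) & !is.na(yv)), r = NA_real_,
                   t = NA_real_, df = NA_integer_, p = NA_real_, stars = "ns",
                   stringsAsFactors = FALSE)
      })
    rec$panel <- panel[k]
    out[[k]] <- rec
  }
  out <- do.call(rbind, out)
  if (holm) out$p_adj <- stats::p.adjust(out$p, method = "holm")
  rownames(out) <- NULL
  out
}
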