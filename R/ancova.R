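#' ANCOVA comparison of WUE-VPD regression lines across treatments
#'
#' Fits a per-group ordinary least-squares line of water use efficiency on
#' vapour pressure deficit, tests homogeneity of slopes (full-interaction
#' model against the common-slope model by F-test), and — when a common
#' slope is tenable — compares the groups' adjusted intercepts pairwise,
#' summarising the comparisons as a compact letter display at alpha = 0.05.
#' Groups sharing a letter do not differ in adjusted intercept. Pairwise
#' tests are unadjusted by default, as in typical SAS ANCOVA output; pass
#' e.g. `adjust = "bonferroni"` (any [stats::p.adjust()] method, or an
#' emmeans adjustment name) to correct.
#'
#' @param data Data frame with columns for VPD, WUE and the grouping factor.
#' @param x,y,group Column names (default `"vpd_kpa"`, `"wue_umol_mmol"`,
#'   `"treatment"`).
#' @param alpha Significance level for the slope-homogeneity gate and the
#'   letter display.
#' @param adjust Multiplicity adjustment for pairwise intercept tests
#'   (default `"none"`).
#' @return Object of class `bb_ancova`: list with `lines` (per-group slope,
#'   slope SE, intercept, intercept SE, r2, regression p and significance
#'   stars), `slope_test` (F, df, p), `slopes_homogeneous`, `letters` (named
#'   character, `NULL` when slopes differ), `pairwise` (data frame of
#'   contrasts), `alpha`.
#' @examples
#' set.seed(1)
#' d <- data.frame(vpd_kpa = runif(60, 0.5, 2),
#'                 treatment = rep(c("FI", "DI", "PRI"), each = 20))
#' d$wue_umol_mmol <- 3 - d$vpd_kpa + rnorm(60, 0, 0.1)
#' wue_vpd_ancova(d)
#' @export
wue_vpd_ancova <- function(data, x = "vpd_kpa", y = "wue_umol_mmol",
                           group = "treatment", alpha = 0.05,
                           adjust = "none") {
  for (col in c(x, y, group))
    if (!col %in% names(data))
      stop("column `", col, "` not found", call. = FALSE)
  d <- data.frame(x = data[[x]], y = data[[y]],
                  g = factor(data[[group]]))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  counts <- table(d$g)
  if (any(counts < 3L))
    stop("every group needs at least 3 observations", call. = FALSE)

  # per-group OLS lines
  lines <- do.call(rbind, lapply(levels(d$g), function(lev) {
    di <- d[d$g == lev, ]
    if (stats::var(di$x) == 0)
      stop("singular design: no VPD variation in group ", lev, call. = FALSE)
    fit <- stats::lm(y ~ x, data = di)
    s <- summary(fit)
    pval <- s$coefficients["x", "Pr(>|t|)"]
    data.frame(group = lev, n = nrow(di),
               slope = s$coefficients["x", "Estimate"],
               slope_se = s$coefficients["x", "Std. Error"],
               intercept = s$coefficients["(Intercept)", "Estimate"],
               intercept_se = s$coefficients["(Intercept)", "Std. Error"],
               r2 = s$r.squared, p = pval,
               stars = p_stars(pval))
  }))

  single <- nlevels(d$g) < 2L
  if (single) {
    out <- list(lines = lines, slope_test = NULL, slopes_homogeneous = TRUE,
                letters = NULL, pairwise = NULL, alpha = alpha)
    class(out) <- "bb_ancova"
    return(out)
  }

  full <- stats::lm(y ~ g * x, data = d)
  common <- stats::lm(y ~ g + x, data = d)
  an <- stats::anova(common, full)
  slope_test <- list(F = an$F[2], df = c(an$Df[2], an$Res.Df[2]),
                     p = an$`Pr(>F)`[2])
  homogeneous <- slope_test$p >= alpha

  letters <- NULL
  pairwise <- NULL
  if (homogeneous) {
    emm <- emmeans::emmeans(common, "g")
    pw <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = adjust))
    pairwise <- pw
    pmat <- pairwise_p_matrix(pw, levels(d$g))
    letters <- compact_letters(pmat, alpha = alpha)
  }

  structure(list(lines = lines, slope_test = slope_test,
                 slopes_homogeneous = homogeneous,
                 letters = letters, pairwise = pairwise, alpha = alpha),
            class = "bb_ancova")
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "ns")))
}

# symmetric matrix of pairwise p-values from an emmeans contrast frame
pairwise_p_matrix <- function(pw, levels) {
  k <- length(levels)
  pm <- matrix(1, k, k, dimnames = list(levels, levels))
  for (i in seq_len(nrow(pw))) {
    parts <- strsplit(pw$contrast[i], " - ", fixed = TRUE)[[1]]
    parts <- gsub("^\\(|\\)$", "", parts)
    pm[parts[1], parts[2]] <- pm[parts[2], parts[1]] <- pw$p.value[i]
  }
  pm
}

# insert-absorb compact letter display from a pairwise p-value matrix
compact_letters <- function(pmat, alpha = 0.05) {
  lev <- rownames(pmat)
  k <- length(lev)
  # start with one group containing everything; split on each significant pair
  groups <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    if (pmat[i, j] < alpha) {
      touched <- vapply(groups, function(g) all(c(i, j) %in% g), logical(1))
      for (gi in which(touched)) {
        g <- groups[[gi]]
        groups[[gi]] <- setdiff(g, j)
        groups <- c(groups, list(setdiff(g, i)))
      }
      # absorb: drop groups contained in another
      keep <- rep(TRUE, length(groups))
      for (a in seq_along(groups)) for (b in seq_along(groups)) {
        if (a != b && keep[a] && keep[b] &&
            all(groups[[a]] %in% groups[[b]])) keep[a] <- FALSE
      }
      groups <- groups[keep]
    }
  }
  groups <- groups[order(vapply(groups, min, numeric(1)))]
  out <- stats::setNames(rep("", k), lev)
  for (gi in seq_along(groups))
    out[groups[[gi]]] <- paste0(out[groups[[gi]]], letters[gi])
  out
}

#' @export
print.bb_ancova <- function(x, ...) {
  cat("WUE ~ VPD regression lines by treatment\n")
  tab <- x$lines
  tab$slope <- sprintf("%.2f +/- %.2f", tab$slope, tab$slope_se)
  tab$intercept <- sprintf("%.2f +/- %.2f", tab$intercept, tab$intercept_se)
  tab$r2 <- sprintf("%.2f%s", tab$r2, tab$stars)
  if (!is.null(x$letters)) tab$letter <- x$letters[tab$group]
  print(tab[, c("group", "n", "slope", "intercept", "r2",
                if (!is.null(x$letters)) "letter")], row.names = FALSE)
  if (!is.null(x$slope_test)) {
    cat(sprintf("Slope homogeneity: F(%d,%d) = %.3f, p = %.3g — %s\n",
                x$slope_test$df[1], x$slope_test$df[2], x$slope_test$F,
                x$slope_test$p,
                if (x$slopes_homogeneous) "common slope tenable"
                else "slopes differ; letters omitted"))
  }
  invisible(x)
}
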