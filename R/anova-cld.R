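#' Two-way ANOVA with Tukey comparisons and compact letter display
#'
#' The variant-by-dose activity tables are analysed with a two-way ANOVA
#' (interaction model) followed by Tukey-adjusted pairwise comparisons of
#' the variants *within* each modulator level, summarised as a compact
#' letter display: variants sharing a letter at a level are not
#' significantly different there.  Sums of squares are type II (via
#' `car::Anova`), which coincides with the classical decomposition for
#' balanced designs and behaves sensibly under mild imbalance; pairwise
#' contrasts use the pooled model variance through `emmeans`.
#'
#' @param data data frame with a numeric response and two factors.
#' @param response,factor1,factor2 column names; `factor1` is the grouping
#'   compared within each level of `factor2` (e.g. protein variant within
#'   ABA concentration).
#' @param alpha significance level for the letter display.
#' @return A list of class `anova_cld`: `anova` (type-II ANOVA table),
#'   `pairwise` (data frame of within-level contrasts with Tukey-adjusted
#'   p-values), `letters` (data frame of factor1, factor2, letters),
#'   `alpha`.
#' @export
anova2_tukey <- function(data, response = "rate", factor1 = "variant",
                         factor2 = "modulator_conc", alpha = 0.05) {
  data <- as.data.frame(data)
  stopifnot(all(c(response, factor1, factor2) %in% names(data)))
  df <- data.frame(
    y = as.numeric(data[[response]]),
    f1 = factor(data[[factor1]]),
    f2 = factor(data[[factor2]])
  )
  tab <- table(df$f1, df$f2)
  if (any(tab == 0L)) {
    idx <- which(tab == 0L, arr.ind = TRUE)
    cells <- apply(idx, 1L, function(ij) {
      paste0(rownames(tab)[ij[1L]], ":", colnames(tab)[ij[2L]])
    })
    stop("empty design cell(s): ", paste(cells, collapse = ", "))
  }
  if (any(tab < 2L)) {
    stop("need >= 2 replicates in every cell for the Tukey comparisons")
  }
  fit <- aov(y ~ f1 * f2, data = df)
  anova_tab <- car::Anova(fit, type = 2)
  rownames(anova_tab) <- sub("^f1$", factor1,
                             sub("^f2$", factor2,
                                 sub("f1:f2", paste0(factor1, ":", factor2),
                                     rownames(anova_tab))))

  emm <- emmeans::emmeans(fit, stats::as.formula("~ f1 | f2"))
  prs <- as.data.frame(summary(
    emmeans::contrast(emm, method = "pairwise", adjust = "tukey")
  ))
  prs$contrast <- as.character(prs$contrast)
  prs$f2 <- as.character(prs$f2)
  names(prs)[names(prs) == "f2"] <- factor2

  groups <- levels(df$f1)
  letters_list <- lapply(levels(df$f2), function(lv) {
    sub <- prs[prs[[factor2]] == lv, , drop = FALSE]
    pmat <- matrix(NA_real_, length(groups), length(groups),
                   dimnames = list(groups, groups))
    for (r in seq_len(nrow(sub))) {
      gg <- strsplit(sub$contrast[r], " - ", fixed = TRUE)[[1L]]
      gg <- gsub("^\\(|\\)$", "", gg)
      pmat[gg[1L], gg[2L]] <- pmat[gg[2L], gg[1L]] <- sub$p.value[r]
    }
    data.frame(f1 = groups, f2 = lv,
               letters = compact_letters(pmat, alpha = alpha),
               stringsAsFactors = FALSE)
  })
  letters_df <- do.call(rbind, letters_list)
  names(letters_df) <- c(factor1, factor2, "letters")

  structure(list(anova = anova_tab, pairwise = prs, letters = letters_df,
                 alpha = alpha),
            class = "anova_cld")
}

#' @export
print.anova_cld <- function(x, ...) {
  cat("<anova_cld> two-way ANOVA (type II) + Tukey letters, alpha = ",
      x$alpha, "\n", sep = "")
  print(x$anova)
  cat("\nCompact letter display (shared letter = not significantly",
      "different):\n")
  print(x$letters, row.names = FALSE)
  invisible(x)
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb algorithm: start from one group set containing
#' everything; for every significant pair, split each set containing both
#' members into two sets each missing one member; drop sets that are
#' subsets of others; assign one letter per surviving set.  The result is
#' consistent with the input by construction — two groups share a letter if
#' and only if their pairwise p-value is not below `alpha`.
#'
#' @param pmat symmetric matrix of pairwise p-values with group names on
#'   both dimnames (diagonal ignored).
#' @param alpha significance level.
#' @return Named character vector of letter strings, one per group.
#' @export
compact_letters <- function(pmat, alpha = 0.05) {
  stopifnot(is.matrix(pmat), nrow(pmat) == ncol(pmat))
  groups <- rownames(pmat)
  if (is.null(groups)) groups <- as.character(seq_len(nrow(pmat)))
  n <- length(groups)
  if (n == 1L) return(setNames("a", groups))

  sig <- which(upper.tri(pmat) & !is.na(pmat) & pmat < alpha, arr.ind = TRUE)
  sets <- list(seq_len(n))
  for (r in seq_len(nrow(sig))) {
    i <- sig[r, 1L]; j <- sig[r, 2L]
    nxt <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        nxt <- c(nxt, list(setdiff(s, i)), list(setdiff(s, j)))
      } else {
        nxt <- c(nxt, list(s))
      }
    }
    # absorb: drop any set contained in another (keeping one of duplicates)
    keep <- rep(TRUE, length(nxt))
    for (a in seq_along(nxt)) {
      for (b in seq_along(nxt)) {
        if (a == b || !keep[a] || !keep[b]) next
        if (all(nxt[[a]] %in% nxt[[b]]) &&
            (length(nxt[[a]]) < length(nxt[[b]]) || a > b)) {
          keep[a] <- FALSE
          break
        }
      }
    }
    sets <- nxt[keep]
  }
  sets <- sets[order(vapply(sets, min, integer(1L)))]
  if (length(sets) > 26L) stop("more than 26 letters needed")
  out <- vapply(seq_len(n), function(g) {
    paste(letters[which(vapply(sets, function(s) g %in% s, logical(1L)))],
          collapse = "")
  }, character(1L))
  setNames(out, groups)
}
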