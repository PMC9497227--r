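# Head-model substitution statistics: difference scores, Pearson
# correlations of ROI activation patterns, the mixed-design ANOVA, and the
# head-model ranking.

#' Collapse per-condition ROI summaries into faces/toys classes
#'
#' @param tbl data.frame with columns \code{subject, group, head_model,
#'   roi, condition, value}.
#' @return data.frame with \code{condition} replaced by \code{stim_class}
#'   (\code{faces}/\code{toys}), values averaged within class.
#' @export
collapseStimClass <- function(tbl) {
  cls <- ifelse(grepl("face", tbl$condition), "faces", "toys")
  agg <- stats::aggregate(
    list(value = tbl$value),
    by = list(subject = tbl$subject, group = tbl$group,
              head_model = tbl$head_model, roi = tbl$roi,
              stim_class = cls),
    FUN = mean)
  agg
}

#' Per-ROI difference scores between two head models
#'
#' Self minus alternative per ROI (within stimulus class when present),
#' plus the mean over ROIs and the within-class means.
#'
#' @param self,alt data.frames with columns \code{roi, value} and
#'   optionally \code{stim_class}, for the same subject.
#' @return list: \code{differences} (per-ROI data.frame with \code{diff}),
#'   \code{mean}, \code{byClass} (named numeric, if classes present).
#' @export
differenceScores <- function(self, alt) {
  keys <- intersect(c("roi", "stim_class"), names(self))
  if (!setequal(do.call(paste, self[keys]), do.call(paste, alt[keys])))
    stop("ROI sets differ between the two summaries")
  m <- merge(self, alt, by = keys, suffixes = c("_self", "_alt"))
  m$diff <- m$value_self - m$value_alt
  out <- list(differences = m[, c(keys, "diff")],
              mean = mean(m$diff, na.rm = TRUE))
  if ("stim_class" %in% keys)
    out$byClass <- tapply(m$diff, m$stim_class, mean, na.rm = TRUE)
  out
}

#' Pearson correlation of ROI activation patterns across head models
#'
#' Pearson product-moment correlation over the paired per-ROI values; by
#' default the faces and toys ROI vectors are concatenated (36 pairs for
#' an 18-ROI atlas). Missing values are excluded pairwise; fewer than 3
#' complete pairs or zero variance on either side yields NA.
#'
#' @param self,alt data.frames as in \code{\link{differenceScores}}.
#' @param pool \code{"concatenate"} (faces and toys stacked) or
#'   \code{"roi_only"} (classes averaged first, 18 pairs).
#' @return numeric correlation (possibly NA).
#' @export
headModelCorrelation <- function(self, alt,
                                 pool = c("concatenate", "roi_only")) {
  pool <- match.arg(pool)
  keys <- intersect(c("roi", "stim_class"), names(self))
  m <- merge(self, alt, by = keys, suffixes = c("_self", "_alt"))
  if (pool == "roi_only" && "stim_class" %in% keys) {
    m <- stats::aggregate(m[, c("value_self", "value_alt")],
                          by = list(roi = m$roi), FUN = mean)
  }
  ok <- stats::complete.cases(m$value_self, m$value_alt)
  x <- m$value_self[ok]
  y <- m$value_alt[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(NA_real_)
  stats::cor(x, y)
}

# orthonormal contrasts spanning the deviation space of p levels
.orthoContrasts <- function(p) {
  q <- qr.Q(qr(cbind(rep(1, p), diag(p))))
  q[, 2:p, drop = FALSE]
}

# Greenhouse-Geisser epsilon for a within-effect stratum, from the pooled
# within-group covariance of subject-level contrast scores; NA when the
# covariance is not estimable (too few subjects for the contrast count)
.ggEpsilon <- function(data, dv, subject, between, withinFactors) {
  cells <- interaction(data[withinFactors], drop = FALSE, lex.order = TRUE)
  lev <- levels(cells)
  wide <- tapply(data[[dv]], list(data[[subject]], cells), mean)
  if (anyNA(wide)) return(NA_real_)
  Cs <- lapply(withinFactors,
               function(f) .orthoContrasts(nlevels(factor(data[[f]]))))
  C <- Reduce(kronecker, Cs)
  scores <- wide %*% C
  grp <- if (length(between)) {
    g <- data[!duplicated(data[[subject]]), ]
    interaction(g[between])[order(match(g[[subject]], rownames(wide)))]
  } else factor(rep(1, nrow(wide)))
  ng <- nlevels(droplevels(grp))
  if (nrow(scores) - ng < ncol(scores)) return(NA_real_)
  S <- matrix(0, ncol(scores), ncol(scores))
  for (g in levels(droplevels(grp))) {
    sc <- scores[grp == g, , drop = FALSE]
    S <- S + crossprod(sweep(sc, 2, colMeans(sc)))
  }
  S <- S / (nrow(scores) - ng)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  sum(ev)^2 / (length(ev) * sum(ev^2))
}

#' Mixed-design repeated-measures ANOVA
#'
#' Univariate mixed-design decomposition with between-subject factors,
#' fully crossed within-subject factors, and error strata
#' subject-within-group crossed with the within-factor combinations
#' (\code{Error(subject/(W1*W2*...))}). F ratios are uncorrected, matching
#' the integer degree-of-freedom presentation of classical mixed ANOVA
#' tables; a Greenhouse-Geisser-corrected p is reported alongside as a
#' diagnostic where the correction is estimable.
#'
#' @param data long-format data.frame.
#' @param dv,subject column names of the response and the subject id.
#' @param between,within character vectors of factor column names.
#' @return data.frame of class \code{anova_table}: \code{effect, df1, df2,
#'   F, p, gg_epsilon, p_gg}, plus a \code{design} attribute.
#' @export
mixedAnova <- function(data, dv, subject, between = character(),
                       within = character()) {
  stopifnot(length(within) >= 1)
  data <- as.data.frame(data)
  for (f in c(subject, between, within)) data[[f]] <- factor(data[[f]])
  # balance: every subject must fill every within-cell exactly once
  cells <- interaction(data[within], drop = FALSE, lex.order = TRUE)
  counts <- table(data[[subject]], cells)
  if (any(counts != 1L)) {
    bad <- which(counts != 1L, arr.ind = TRUE)
    stop("unbalanced within-subject design; missing or duplicated cells: ",
         paste(utils::head(paste(rownames(counts)[bad[, 1]],
                                 colnames(counts)[bad[, 2]], sep = " x "),
                           5), collapse = ", "))
  }
  if (length(between)) {
    grpPer <- tapply(as.character(interaction(data[between], drop = TRUE)),
                     data[[subject]], function(x) unique(x))
    if (any(lengths(grpPer) != 1L))
      stop("each subject must belong to exactly one between-group cell")
    if (any(table(unlist(grpPer)) < 2L))
      stop("need at least 2 subjects per between-group cell")
  }
  fx <- paste(c(between, within), collapse = " * ")
  err <- paste0("Error(", subject, "/(", paste(within, collapse = " * "),
                "))")
  form <- stats::as.formula(paste(dv, "~", fx, "+", err))
  fit <- stats::aov(form, data = data)
  out <- list()
  for (stratum in names(summary(fit))) {
    tab <- summary(fit)[[stratum]][[1]]
    nm <- trimws(rownames(tab))
    resid <- nm == "Residuals"
    df2 <- tab[resid, "Df"]
    wf <- strsplit(sub("^Error: ", "", stratum), ":")[[1]]
    wf <- intersect(wf, within)
    eps <- if (length(wf)) .ggEpsilon(data, dv, subject, between, wf)
           else NA_real_
    for (i in which(!resid)) {
      Fv <- tab[i, "F value"]
      out[[length(out) + 1L]] <- data.frame(
        effect = gsub(":", " x ", nm[i]), df1 = tab[i, "Df"], df2 = df2,
        F = Fv, p = tab[i, "Pr(>F)"], gg_epsilon = eps,
        p_gg = if (!is.na(eps) && is.finite(Fv))
          stats::pf(Fv, eps * tab[i, "Df"], eps * df2, lower.tail = FALSE)
        else NA_real_)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "design") <- list(
    between = lapply(data[between], levels),
    within = lapply(data[within], levels),
    groupSizes = if (length(between))
      table(interaction((data[!duplicated(data[[subject]]), ])[between]))
    else length(unique(data[[subject]])))
  class(res) <- c("anova_table", "data.frame")
  res
}

#' Compare substitute head models against the Self model
#'
#' Computes, per subject, the difference scores and the pattern
#' correlation between the Self head model and each alternative, and
#' aggregates them into the group-level mean/SD tables and the head-model
#' ranking (alternatives ordered by mean absolute difference score
#' ascending, ties broken by mean correlation descending).
#'
#' @param tbl data.frame with columns \code{subject, group, head_model,
#'   roi, condition, value}; \code{head_model == "Self"} rows are the
#'   reference.
#' @param pool correlation pooling, see \code{\link{headModelCorrelation}}.
#' @return list of class \code{headmodel_comparison}: \code{perSubject},
#'   \code{meanDifferences} (per model: mean/faces/toys difference),
#'   \code{roiMeans} (group x ROI x model mean activation),
#'   \code{correlations} (mean (SD) r per model overall and by group),
#'   \code{ranking}, \code{winner}.
#' @export
compareHeadModels <- function(tbl, pool = c("concatenate", "roi_only")) {
  pool <- match.arg(pool)
  cls <- collapseStimClass(tbl)
  models <- setdiff(unique(cls$head_model), "Self")
  if (!length(models)) stop("no alternative head models to compare")
  per <- list()
  for (s in unique(cls$subject)) {
    sub <- cls[cls$subject == s, ]
    self <- sub[sub$head_model == "Self", c("roi", "stim_class", "value")]
    for (hm in models) {
      alt <- sub[sub$head_model == hm, c("roi", "stim_class", "value")]
      if (!nrow(alt)) next
      d <- differenceScores(self, alt)
      r <- headModelCorrelation(self, alt, pool)
      per[[length(per) + 1L]] <- data.frame(
        subject = s, group = sub$group[1], head_model = hm,
        mean_diff = d$mean, faces_diff = unname(d$byClass["faces"]),
        toys_diff = unname(d$byClass["toys"]),
        mean_abs_diff = mean(abs(d$differences$diff), na.rm = TRUE),
        r = r)
    }
  }
  per <- do.call(rbind, per)
  selfLevel <- stats::aggregate(
    list(value = cls$value[cls$head_model == "Self"]),
    by = list(stim_class = cls$stim_class[cls$head_model == "Self"]),
    FUN = mean, na.rm = TRUE)
  meanDifferences <- do.call(rbind, lapply(models, function(hm) {
    p <- per[per$head_model == hm, ]
    data.frame(head_model = hm, mean = mean(p$mean_diff, na.rm = TRUE),
               faces = mean(p$faces_diff, na.rm = TRUE),
               toys = mean(p$toys_diff, na.rm = TRUE))
  }))
  roiMeans <- stats::aggregate(
    list(value = cls$value),
    by = list(group = cls$group, head_model = cls$head_model,
              roi = cls$roi), FUN = mean, na.rm = TRUE)
  corStats <- function(p) c(mean = mean(p$r, na.rm = TRUE),
                            sd = stats::sd(p$r, na.rm = TRUE))
  correlations <- do.call(rbind, lapply(models, function(hm) {
    p <- per[per$head_model == hm, ]
    row <- data.frame(head_model = hm, r_mean = corStats(p)[["mean"]],
                      r_sd = corStats(p)[["sd"]])
    for (g in unique(per$group)) {
      cs <- corStats(p[p$group == g, ])
      row[[paste0("r_mean_", g)]] <- cs[["mean"]]
      row[[paste0("r_sd_", g)]] <- cs[["sd"]]
    }
    row
  }))
  ranking <- do.call(rbind, lapply(models, function(hm) {
    p <- per[per$head_model == hm, ]
    data.frame(head_model = hm,
               mean_abs_diff = mean(p$mean_abs_diff, na.rm = TRUE),
               mean_r = mean(p$r, na.rm = TRUE))
  }))
  ranking <- ranking[order(ranking$mean_abs_diff, -ranking$mean_r), ]
  rownames(ranking) <- NULL
  structure(list(perSubject = per, selfLevel = selfLevel,
                 meanDifferences = meanDifferences, roiMeans = roiMeans,
                 correlations = correlations, ranking = ranking,
                 winner = ranking$head_model[1]),
            class = "headmodel_comparison")
}

#' Rank substitute head models
#'
#' @param comparison a \code{headmodel_comparison} (or its
#'   \code{perSubject} table).
#' @return the ranking data.frame, best model first.
#' @export
rankHeadModels <- function(comparison) {
  if (inherits(comparison, "headmodel_comparison"))
    return(comparison$ranking)
  per <- comparison
  ranking <- do.call(rbind, lapply(unique(per$head_model), function(hm) {
    p <- per[per$head_model == hm, ]
    data.frame(head_model = hm,
               mean_abs_diff = mean(p$mean_abs_diff, na.rm = TRUE),
               mean_r = mean(p$r, na.rm = TRUE))
  }))
  ranking <- ranking[order(ranking$mean_abs_diff, -ranking$mean_r), ]
  rownames(ranking) <- NULL
  ranking
}

#' @export
print.headmodel_comparison <- function(x, ...) {
  cat("Head-model comparison over", length(unique(x$perSubject$subject)),
      "subjects\n")
  cat("Ranking (mean |difference| ascending, tie-break mean r):\n")
  print(x$ranking, row.names = FALSE)
  cat("Best substitute:", x$winner, "\n")
  invisible(x)
}
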