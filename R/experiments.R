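# Seeded simulation experiments: the head-model ranking recovery study
# (the synthetic analogue of the large-pool-template finding) and the
# null calibration of the mixed ANOVA.

#' Head-model ranking recovery experiment
#'
#' Repeatedly generates small cohorts and ranks four substitute head
#' models against each subject's Self model: a large-pool template drawn
#' from the subjects' own population, a small-pool template from a mildly
#' perturbed population, and two mismatched-geometry templates from
#' populations with inflated head size (older-age stand-ins). Reports how
#' often the large-pool same-population template wins the ranking.
#'
#' @param nCohorts number of seeded replicate cohorts.
#' @param seed master seed.
#' @param nSubjects subjects per cohort (one group).
#' @param group generating group for subjects and the large pool.
#' @param pools named list of pool specs \code{list(n, radiusScale)} for
#'   \code{LargePool}, \code{SmallPool}, \code{MidMismatch},
#'   \code{FarMismatch}.
#' @param gridDim,voxelSize,stride problem-size controls for the replicate
#'   cohorts (coarser than the single-run defaults so that many cohorts
#'   stay cheap).
#' @param alpha eLORETA regularization.
#' @return list: \code{winRate}, \code{wins}, \code{nCohorts},
#'   \code{winners} (per cohort), \code{rankings}.
#' @export
headModelRankingExperiment <- function(nCohorts = 50L, seed = 1L,
                                       nSubjects = 3L, group = "FXS",
                                       pools = list(
                                         LargePool = list(n = 12L, radiusScale = 1),
                                         SmallPool = list(n = 4L, radiusScale = 1.05),
                                         MidMismatch = list(n = 6L, radiusScale = 1.15),
                                         FarMismatch = list(n = 6L, radiusScale = 1.3)),
                                       gridDim = 65L, voxelSize = 3.5,
                                       stride = 2L, alpha = 0.05) {
  winners <- character(nCohorts)
  rankings <- vector("list", nCohorts)
  inverse <- list(alpha = alpha, tol = 1e-6, maxIter = 100L)
  for (i in seq_len(nCohorts)) {
    cfg <- cohortConfig(nPerGroup = stats::setNames(nSubjects, group),
                        gridDim = gridDim, voxelSize = voxelSize,
                        seed = seed + i)
    cohort <- makeCohort(cfg, sourceStride = stride)
    tmplModels <- list()
    for (nm in names(pools)) {
      p <- pools[[nm]]
      vols <- .drawPool(group, cfg, p$n, radiusScale = p$radiusScale)
      tpl <- buildAverageTemplate(vols, tol = 1e-3, maxIter = 6L)
      tmplModels[[nm]] <- .templateHeadModel(templateVolume(tpl),
                                             cohort$sourceGrid,
                                             cohort$template, inverse)
    }
    peaks <- peakTable(cohort)
    rows <- list()
    for (subj in cohort$subjects) {
      selfOp <- buildEloretaOperator(subj$leadField, alpha = alpha)
      rows[[paste0(subj$id, "-Self")]] <-
        .subjectRoiRows(subj, "Self", selfOp, subj$leadField,
                        cohort$atlas, peaks)
      for (nm in names(tmplModels))
        rows[[paste0(subj$id, "-", nm)]] <-
          .subjectRoiRows(subj, nm, tmplModels[[nm]]$operator,
                          tmplModels[[nm]]$leadField, cohort$atlas, peaks)
    }
    cmp <- compareHeadModels(do.call(rbind, rows))
    winners[i] <- cmp$winner
    rankings[[i]] <- cmp$ranking
  }
  list(winRate = mean(winners == "LargePool"),
       wins = sum(winners == "LargePool"), nCohorts = nCohorts,
       winners = winners, rankings = rankings)
}

#' Null calibration of the mixed-ANOVA head-model effect
#'
#' Simulates the head-model comparison design with no head-model effect
#' (subject random intercepts plus noise only) and measures the type-I
#' rate and mean F of the head-model main effect at the nominal level.
#'
#' @param nRep number of replicates.
#' @param seed master seed.
#' @param groupSizes subjects per between-group level.
#' @param nModels within-factor (head model) levels.
#' @param level nominal significance level.
#' @param subjectSd,noiseSd random intercept and residual SDs.
#' @return list: \code{typeIRate}, \code{meanF}, \code{nRep}, \code{df}.
#' @export
nullAnovaCalibration <- function(nRep = 500L, seed = 1L,
                                 groupSizes = c(8L, 11L), nModels = 6L,
                                 level = 0.05, subjectSd = 1,
                                 noiseSd = 1) {
  set.seed(seed)
  nSub <- sum(groupSizes)
  grp <- rep(paste0("g", seq_along(groupSizes)), groupSizes)
  design <- expand.grid(subject = seq_len(nSub),
                        head_model = paste0("hm", seq_len(nModels)))
  design$group <- grp[design$subject]
  pvals <- numeric(nRep)
  fvals <- numeric(nRep)
  df <- NULL
  for (r in seq_len(nRep)) {
    b <- stats::rnorm(nSub, 0, subjectSd)
    design$value <- b[design$subject] +
      stats::rnorm(nrow(design), 0, noiseSd)
    a <- mixedAnova(design, "value", "subject", between = "group",
                    within = "head_model")
    row <- a[a$effect == "head_model", ]
    pvals[r] <- row$p
    fvals[r] <- row$F
    if (is.null(df)) df <- c(row$df1, row$df2)
  }
  list(typeIRate = mean(pvals < level), meanF = mean(fvals), nRep = nRep,
       df = df)
}
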