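# ---- phantom evaluation pipelines ------------------------------------------
#
# These functions wire the phantom world into the two evaluation designs:
# (volume -> surface) project per-subject parcellations into the template
# volume with each subject's true warp, average into per-structure
# probabilistic maps, project those through a candidate mapping and score
# them with the normalized absolute difference against the surface truth;
# (surface -> volume) combine the per-subject surface parcellations into a
# winner-takes-all template-surface parcellation, project it through a
# candidate surface-to-volume mapping and score per-structure Dice against
# the winner-takes-all volumetric truth.

#' Evaluation inputs from a phantom cohort
#'
#' @param cohortData output of [makeCohort()].
#' @return list with `volProb` (volumetric [ProbabilisticMap-class]),
#'   `surfProb` (surface truth [ProbabilisticMap-class]), `surfWTA` and
#'   `volWTA` ([Parcellation-class]).
#' @export
phantomEvalInputs <- function(cohortData) {
  template <- cohortData$template
  grid <- templateGridSpec(template)
  volSpace <- list(type = "volume", dim = grid$dim, affine = grid$affine)
  vtxSpace <- list(type = "surface",
                   nVertices = nrow(template$sphere@vertices))
  subjParcs <- makeSubjectParcellations(cohortData)
  volParcs <- mapply(function(p, b) {
    img <- VolumeImage(array(p@labels, dim = grid$dim), grid$affine)
    onTemplate <- resampleVolume(img, b@volChain, target = grid,
                                 interp = "nearest")
    Parcellation(onTemplate@data, template$labels, volSpace)
  }, subjParcs, cohortData$cohort, SIMPLIFY = FALSE)
  surfParcs <- lapply(cohortData$cohort, function(b) {
    lab <- resampleToTemplate(b@reg, template$vertexParcellation@labels,
                              interp = "nearest")
    Parcellation(lab, template$labels, vtxSpace)
  })
  volProb <- makeProbMaps(volParcs)
  surfProb <- makeProbMaps(surfParcs)
  list(volProb = volProb, surfProb = surfProb,
       surfWTA = winnerTakesAll(surfProb),
       volWTA = winnerTakesAll(volProb))
}

vertexHemispheres <- function(template) {
  ifelse(template$sphere@vertices[, 1] < 0, "lh", "rh")
}

voxelHemispheres <- function(template) {
  grid <- templateGridSpec(template)
  ifelse(gridCenters(grid$dim, grid$affine)[, 1] < 0, "lh", "rh")
}

#' Normalized-absolute-difference table for a volume-to-surface mapping
#'
#' Projects each structure's volumetric probabilistic map through the
#' mapping (trilinear) and scores it against the surface truth per
#' structure and hemisphere. Structure/hemisphere cells without ground-
#' truth mass are skipped.
#'
#' @param mapping a [VolToSurfMapping-class].
#' @param inputs output of [phantomEvalInputs()].
#' @param template the phantom template.
#' @param approach approach name recorded in the table.
#' @param split `"hemisphere"` scores each structure per half-shell (the
#'   replicate used for hemisphere averaging); `"none"` scores whole
#'   structures.
#' @return a [metricTable()] data.frame (`replicate` = hemisphere).
#' @export
nadTable <- function(mapping, inputs, template, approach = "rf",
                     split = c("hemisphere", "none")) {
  split <- match.arg(split)
  grid <- templateGridSpec(template)
  hemi <- if (split == "hemisphere") vertexHemispheres(template)
          else rep("all", nrow(template$sphere@vertices))
  rows <- list()
  for (j in seq_along(inputs$volProb@labels)) {
    lab <- inputs$volProb@labels[j]
    vol <- VolumeImage(array(inputs$volProb@probs[, j], dim = grid$dim),
                       grid$affine)
    proj <- suppressWarnings(projectVolToSurf(vol, mapping, "trilinear"))
    truth <- inputs$surfProb@probs[, j]
    for (h in unique(hemi)) {
      idx <- hemi == h
      if (sum(truth[idx]) <= 0) next
      rows[[length(rows) + 1L]] <-
        data.frame(structure = lab, approach = approach, replicate = h,
                   value = nad(proj[idx], truth[idx]),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  metricTable(out$structure, out$approach, out$replicate, out$value,
              metric = "nad", n = inputs$volProb@nSubjects)
}

#' Dice table for a surface-to-volume mapping
#'
#' Projects the winner-takes-all template-surface parcellation through the
#' mapping (nearest) and scores per-structure, per-hemisphere Dice against
#' the winner-takes-all volumetric truth. Structures absent from both
#' parcellations in a hemisphere are skipped.
#'
#' @inheritParams nadTable
#' @param mapping a finalized [SurfToVolMapping-class].
#' @return a [metricTable()] data.frame (`replicate` = hemisphere).
#' @export
diceTable <- function(mapping, inputs, template, approach = "rf",
                      split = c("hemisphere", "none")) {
  split <- match.arg(split)
  proj <- projectSurfToVol(inputs$surfWTA@labels, mapping, "nearest")
  truth <- inputs$volWTA@labels
  hemi <- if (split == "hemisphere") voxelHemispheres(template)
          else rep("all", length(truth))
  rows <- list()
  for (lab in inputs$volProb@labels) {
    for (h in unique(hemi)) {
      idx <- hemi == h
      A <- as.vector(proj@data)[idx] == lab
      B <- truth[idx] == lab
      if (!any(A) && !any(B)) next
      rows[[length(rows) + 1L]] <-
        data.frame(structure = lab, approach = approach, replicate = h,
                   value = 2 * sum(A & B) / (sum(A) + sum(B)),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  metricTable(out$structure, out$approach, out$replicate, out$value,
              metric = "dice", n = mapping@nSubjects)
}

#' Per-vertex mapping error against ground truth
#'
#' @param mapping a [VolToSurfMapping-class].
#' @param truth the ground-truth [VolToSurfMapping-class].
#' @return vector of per-vertex Euclidean errors (mm).
#' @export
mappingError <- function(mapping, truth) {
  rowNorms(mapping@coords - truth@coords)
}

# Independent evaluation cohort: same phantom world, disjoint seed stream.
# Mirrors the training/test split of the source design: the probabilistic
# maps that score a mapping must come from subjects that did not build it,
# otherwise shared registration errors bias the scores toward small
# cohorts.
evalCohortSpec <- function(spec, nSubjects = spec@nSubjects) {
  phantomSpec(gridShape = spec@gridShape, voxelSize = spec@voxelSize,
              rIn = spec@rIn, rOut = spec@rOut, nParcels = spec@nParcels,
              nSubjects = nSubjects, amplitude = spec@amplitude,
              jitterDeg = spec@jitterDeg,
              seed = as.integer((spec@seed + 710927L) %% 2147480009L),
              subdivisions = spec@subdivisions, recenter = spec@recenter)
}

#' Build all three mappings and compare them on one phantom cohort
#'
#' Runs registration fusion, the affine baseline and the single-
#' registration baseline on the same training cohort, evaluates both
#' directions against probabilistic maps from an independent evaluation
#' cohort (the phantom analogue of a held-out test set), and performs all
#' pairwise paired t-tests with Benjamini-Hochberg correction.
#'
#' @param spec a [PhantomSpec-class].
#' @param tightThresh,looseThresh coverage thresholds.
#' @param baselineAmplitude nonlinear distortion amplitude (mm) of the
#'   surface-template volume used by the affine baseline.
#' @param q false-discovery rate.
#' @return list with `nadTable`, `diceTable`, `nadComparison`,
#'   `diceComparison`, the three mapping sets, and the cohort data.
#' @export
phantomMethodComparison <- function(spec, tightThresh = 0.5,
                                    looseThresh = 0.15,
                                    baselineAmplitude = 3, q = 0.05) {
  cohortData <- makeCohort(spec)
  template <- cohortData$template
  grid <- templateGridSpec(template)
  evalData <- makeCohort(evalCohortSpec(spec))
  inputs <- phantomEvalInputs(evalData)

  rfV2S <- buildVol2Surf(cohortData$cohort, template$sphere)
  rfS2V <- finalizeSurf2Vol(
    dilateMapping(buildSurf2Vol(cohortData$cohort, grid, tightThresh,
                                looseThresh)),
    template$sphere)

  singleBundle <- makeSubject(spec, spec@nSubjects + 1L, template)$bundle
  single <- buildSingleRegistrationBaseline(singleBundle, template$sphere,
                                            grid, tightThresh, looseThresh)

  bi <- makeBaselineInputs(spec, template, amplitude = baselineAmplitude)
  affine <- buildAffineBaseline(bi$affine, bi$templateSurfaceMap, grid,
                                tightThresh, looseThresh)

  nadTbl <- rbind(nadTable(rfV2S, inputs, template, "rf"),
                  nadTable(affine$vol2surf, inputs, template, "affine"),
                  nadTable(single$vol2surf, inputs, template, "single"))
  attr(nadTbl, "metric") <- "nad"
  diceTbl <- rbind(diceTable(rfS2V, inputs, template, "rf"),
                   diceTable(affine$surf2vol, inputs, template, "affine"),
                   diceTable(single$surf2vol, inputs, template, "single"))
  attr(diceTbl, "metric") <- "dice"

  list(nadTable = nadTbl, diceTable = diceTbl,
       nadComparison = compareApproaches(nadTbl, q, higherBetter = FALSE),
       diceComparison = compareApproaches(diceTbl, q, higherBetter = TRUE),
       rf = list(vol2surf = rfV2S, surf2vol = rfS2V),
       affine = affine, single = single,
       cohortData = cohortData, inputs = inputs)
}

#' Convergence of registration fusion with cohort size
#'
#' For every seed, generates a training cohort of `max(sizes)` subjects
#' (prefix-stable, so the first n subjects form the size-n cohort), builds
#' the fused mapping from each prefix, and records the per-structure
#' normalized absolute difference of the projected probabilistic maps plus
#' the mean vertex mapping error against ground truth. The evaluation
#' inputs (the probabilistic maps) come from an independent evaluation
#' cohort held fixed across sizes — the phantom analogue of scoring every
#' mapping on the same test set.
#'
#' @param spec a [PhantomSpec-class]; `nSubjects` is overridden per run,
#'   and `spec@seed` keys the shared evaluation cohort.
#' @param sizes ascending cohort sizes.
#' @param seeds training-cohort master seeds, one replicate per seed.
#' @return a [metricTable()] (`approach` = cohort size, `replicate` =
#'   seed-hemisphere) with attributes `mapError` (data.frame: size, seed,
#'   meanError), `sizeMeans` (seed-averaged mean per size),
#'   `nonIncreasing`, and `fracImproved` (share of seeds whose largest-size
#'   values beat the smallest-size values, for NAD and mapping error).
#' @export
convergenceExperiment <- function(spec, sizes = c(4L, 8L, 16L, 32L),
                                  seeds = 1:10) {
  if (is.unsorted(sizes)) stop("sizes must be ascending")
  specFor <- function(seed) phantomSpec(
    gridShape = spec@gridShape, voxelSize = spec@voxelSize, rIn = spec@rIn,
    rOut = spec@rOut, nParcels = spec@nParcels, nSubjects = max(sizes),
    amplitude = spec@amplitude, jitterDeg = spec@jitterDeg, seed = seed,
    subdivisions = spec@subdivisions, recenter = spec@recenter)
  # one fixed evaluation cohort scores every curve (a held-out test set)
  inputs <- phantomEvalInputs(makeCohort(evalCohortSpec(specFor(spec@seed))))
  rows <- list()
  errRows <- list()
  for (seed in seeds) {
    cohortData <- makeCohort(specFor(seed))
    template <- cohortData$template
    truth <- cohortData$truth$vol2surf
    # per-subject vertex coordinates once; prefix means by running sums
    # (same per-vertex exclusion rule as buildVol2Surf for out-of-hull rows)
    perSubj <- lapply(cohortData$cohort, subjectVertexCoords)
    run <- matrix(0, nrow(perSubj[[1]]), 3)
    cnt <- integer(nrow(run))
    nextIdx <- 1L
    for (n in sizes) {
      while (nextIdx <= n) {
        q <- perSubj[[nextIdx]]
        ok <- is.finite(q[, 1])
        run[ok, ] <- run[ok, ] + q[ok, , drop = FALSE]
        cnt <- cnt + ok
        nextIdx <- nextIdx + 1L
      }
      if (any(cnt == 0L))
        stop("vertex with no contributing subject in convergence run")
      m <- new("VolToSurfMapping", coords = run / cnt,
               nSubjects = n, nContributing = cnt)
      tbl <- nadTable(m, inputs, template, approach = sprintf("n%03d", n))
      tbl$replicate <- paste0("seed", seed, "-", tbl$replicate)
      rows[[length(rows) + 1L]] <- as.data.frame(tbl)
      errRows[[length(errRows) + 1L]] <-
        data.frame(size = n, seed = seed,
                   meanError = mean(mappingError(m, truth)))
    }
  }
  tbl <- do.call(rbind, rows)
  out <- metricTable(tbl$structure, tbl$approach, tbl$replicate, tbl$value,
                     metric = "nad", n = max(sizes))
  err <- do.call(rbind, errRows)
  nadSize <- as.integer(sub("^n", "", tbl$approach))
  nadAgg <- tapply(tbl$value, list(nadSize, sub("-.*", "", tbl$replicate)),
                   mean)
  sizeMeans <- rowMeans(nadAgg)
  improvedNad <- mean(nadAgg[nrow(nadAgg), ] < nadAgg[1, ])
  errAgg <- tapply(err$meanError, list(err$size, err$seed), mean)
  improvedErr <- mean(errAgg[nrow(errAgg), ] < errAgg[1, ])
  attr(out, "mapError") <- err
  attr(out, "sizeMeans") <- sizeMeans
  attr(out, "errSizeMeans") <- rowMeans(errAgg)
  attr(out, "nonIncreasing") <- all(diff(sizeMeans) <= 1e-12)
  attr(out, "fracImproved") <- c(nad = improvedNad, mapError = improvedErr)
  out
}
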