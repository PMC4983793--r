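pipelineLog <- function(config, ...) {
  if (identical(config$logLevel, "info")) message(sprintf(...))
}

quantifyOneImage <- function(path, config) {
  img <- readFluorImage(path)
  regions <- detectBeads(img, config$seg)
  qc <- checkBeadDistribution(regions, config$minBeads,
                              config$maxClumpFraction)
  beads <- ringBodyStats(img, regions, config$rim)
  res <- imageFlipSignal(img, regions, config$rim)
  list(result = res, qc = qc, beads = beads, regions = regions)
}

#' Run the full FLIP image-analysis pipeline
#'
#' For every condition in the manifest: read each image, detect and filter
#' beads, run the bead-distribution QC, quantify per-bead ring/body
#' statistics, merge replicates, and subtract the matched IgG control.
#' Conditions without a control are reported raw-only with a warning (an
#' absent control is never treated as zero). With `mergeOrder =
#' "subtract_then_merge"` and matching test/control replicate indices, the
#' subtraction is done pairwise per replicate before merging.
#'
#' @param manifest data.frame from [readManifest()], or a path to the CSV.
#' @param config From [flipConfig()] or [readConfig()].
#' @param outDir Optional output directory; when given, writes
#'   `conditions.csv` (per-condition signals), `beads.csv` (per-bead
#'   statistics) and `qc.csv`, each stamped with the config hash and
#'   package version.
#' @return List: `conditions` (data.frame: condition, rawSignal,
#'   controlSignal, correctedSignal, nBeads, variability, monolayerFlag),
#'   `results` (named list of [FlipResult-class]), `beads`, `qc`,
#'   `provenance` (configHash, packageVersion).
#' @export
runPipeline <- function(manifest, config = flipConfig(), outDir = NULL) {
  if (is.character(manifest)) manifest <- readManifest(manifest)
  stopifnot(is.data.frame(manifest), nrow(manifest) > 0)
  provenance <- list(configHash = objectHash(config),
                     packageVersion = as.character(
                       utils::packageVersion("FLIPimage")))

  conditions <- unique(manifest$condition)
  allBeads <- list(); allQC <- list(); results <- list()
  rows <- list()
  for (cond in conditions) {
    sub <- manifest[manifest$condition == cond, , drop = FALSE]
    testRows <- sub[sub$role == "test", , drop = FALSE]
    ctlRows <- sub[sub$role == "control", , drop = FALSE]

    quantRole <- function(rws, role) {
      lapply(seq_len(nrow(rws)), function(i) {
        q <- quantifyOneImage(rws$path[i], config)
        pipelineLog(config,
                    "[%s/%s rep %s] %d beads retained of %d objects%s",
                    cond, role, rws$replicate[i], q$qc$nRetained,
                    q$qc$nObjects,
                    if (q$qc$monolayerFlag) {
                      paste0(" (QC: ", paste(q$qc$flagReasons, collapse = ","), ")")
                    } else "")
        b <- q$beads
        if (nrow(b)) {
          b <- cbind(condition = cond, role = role,
                     replicate = rws$replicate[i], b)
        }
        allBeads[[length(allBeads) + 1]] <<- b
        allQC[[length(allQC) + 1]] <<- data.frame(
          condition = cond, role = role, replicate = rws$replicate[i],
          nRetained = q$qc$nRetained, nObjects = q$qc$nObjects,
          coverage = q$qc$coverage, clumpFraction = q$qc$clumpFraction,
          monolayerFlag = q$qc$monolayerFlag,
          flagReasons = paste(q$qc$flagReasons, collapse = ";"))
        q$result
      })
    }

    tests <- quantRole(testRows, "test")
    ctls <- if (nrow(ctlRows)) quantRole(ctlRows, "control") else list()

    res <- if (length(ctls) == 0) {
      warning("condition '", cond,
              "' has no control image; reporting raw signal only")
      replicateMerge(tests)
    } else if (config$mergeOrder == "subtract_then_merge" &&
               length(tests) == length(ctls) &&
               setequal(testRows$replicate, ctlRows$replicate)) {
      ord <- match(sort(testRows$replicate), testRows$replicate)
      ordC <- match(sort(ctlRows$replicate), ctlRows$replicate)
      replicateMerge(Map(controlSubtract, tests[ord], ctls[ordC]))
    } else {
      controlSubtract(replicateMerge(tests), replicateMerge(ctls))
    }
    results[[cond]] <- res
    rows[[cond]] <- data.frame(
      condition = cond, rawSignal = rawSignal(res),
      controlSignal = controlSignal(res),
      correctedSignal = correctedSignal(res), nBeads = nBeads(res),
      variability = variability(res))
  }

  condTable <- do.call(rbind, rows)
  rownames(condTable) <- NULL
  qcTable <- do.call(rbind, allQC)
  beadTable <- do.call(rbind, allBeads[vapply(allBeads, NROW, 1L) > 0])
  condTable$monolayerFlag <- vapply(condTable$condition, function(cn) {
    any(qcTable$monolayerFlag[qcTable$condition == cn])
  }, logical(1))

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    stamp <- function(df) {
      df$configHash <- provenance$configHash
      df$packageVersion <- provenance$packageVersion
      df
    }
    utils::write.csv(stamp(condTable),
                     file.path(outDir, "conditions.csv"), row.names = FALSE)
    if (!is.null(beadTable)) {
      utils::write.csv(stamp(beadTable), file.path(outDir, "beads.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(stamp(qcTable), file.path(outDir, "qc.csv"),
                     row.names = FALSE)
  }

  list(conditions = condTable, results = results, beads = beadTable,
       qc = qcTable, provenance = provenance)
}
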