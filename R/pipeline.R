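## Batch orchestration: field discovery -> detection -> segmentation ->
## assignment -> aggregation -> statistics, under one frozen parameter set.

#' Construct a frozen batch configuration
#'
#' Detection and segmentation parameters are set once, on a sample image
#' (see [tunePreview()]), and then applied unchanged to the entire assay
#' batch; [runBatch()] serialises the configuration verbatim into the
#' output directory.
#'
#' @param thresholds Named numeric(3): DoG-intensity detection thresholds
#'   `th1`, `th2`, `th4`.
#' @param dog A [DoGParams-class].
#' @param segmentation A [SegmentationParams-class].
#' @param maxDist Dot-to-nucleus assignment radius in pixels (default 10).
#' @param minSeparation Spot non-maximum-suppression radius (default 2).
#' @param positivityThresholds Named numeric, minimum copies per marker
#'   (default 1 for every marker).
#' @param markerMaps Named list of per-assay channel-to-marker maps.
#' @param seed Integer seed recorded with the run.
#' @return A [RunConfig-class].
#' @export
punctaConfig <- function(thresholds = c(th1 = 0.25, th2 = 0.25, th4 = 0.25),
                         dog = dogParams(),
                         segmentation = segmentationParams(),
                         maxDist = 10, minSeparation = 2,
                         positivityThresholds = c(TH = 1, GFAP = 1,
                                                  zif268 = 1, Arc = 1),
                         markerMaps = list(A = defaultMarkerMap("A"),
                                           B = defaultMarkerMap("B")),
                         seed = 1) {
  new("RunConfig", dog = dog, thresholds = thresholds[c("th1", "th2", "th4")],
      segmentation = segmentation, maxDist = maxDist,
      minSeparation = minSeparation,
      positivityThresholds = positivityThresholds,
      markerMaps = markerMaps, seed = as.integer(seed))
}

configToList <- function(config) {
  list(dog = list(sigma_small = config@dog@sigmaSmall,
                  sigma_large = config@dog@sigmaLarge),
       thresholds = as.list(config@thresholds),
       segmentation = list(dapi_sigma = config@segmentation@dapiSigma,
                           min_area = config@segmentation@minArea,
                           backend = config@segmentation@backend),
       max_dist = config@maxDist,
       min_separation = config@minSeparation,
       positivity_thresholds = as.list(config@positivityThresholds),
       marker_maps = lapply(config@markerMaps, as.list),
       seed = config@seed)
}

#' Read a batch configuration from YAML
#'
#' @param path YAML file as written by [runBatch()] (`config.yaml`), with
#'   top-level keys `dog`, `thresholds`, `segmentation`, `max_dist`,
#'   `min_separation`, `positivity_thresholds`, `marker_maps`, `seed`.
#' @return A [RunConfig-class].
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  punctaConfig(
    thresholds = unlist(y$thresholds),
    dog = dogParams(y$dog$sigma_small %||% 0.5, y$dog$sigma_large %||% 3),
    segmentation = segmentationParams(
      dapiSigma = y$segmentation$dapi_sigma %||% 7,
      minArea = y$segmentation$min_area %||% 150,
      backend = y$segmentation$backend %||% "quantise-watershed"),
    maxDist = y$max_dist %||% 10,
    minSeparation = y$min_separation %||% 2,
    positivityThresholds = unlist(y$positivity_thresholds %||%
                                    list(TH = 1, GFAP = 1, zif268 = 1,
                                         Arc = 1)),
    markerMaps = if (is.null(y$marker_maps))
      list(A = defaultMarkerMap("A"), B = defaultMarkerMap("B"))
    else lapply(y$marker_maps, unlist),
    seed = y$seed %||% 1)
}

processField <- function(field, config, fieldId) {
  ss <- detectFieldSpots(field, config@thresholds, config@dog,
                         config@minSeparation)
  seg <- segmentNuclei(channelImage(field, 3), config@segmentation)
  cct <- assignSpots(ss, seg, config@maxDist, fieldId)
  list(spots = ss, segmentation = seg, counts = cct)
}

#' Run a frozen-parameter batch analysis
#'
#' Processes every field of the manifest with one parameter set: DoG
#' filtering and per-channel thresholding, nuclei segmentation, 10-px
#' dot-to-nucleus assignment, per-animal aggregation, and (when a behaviour
#' table is supplied) quartile phenotyping, Kruskal-Wallis group
#' comparisons of per-channel totals, and session-by-metric Spearman/BH
#' correlation matrices. Unreadable fields are skipped with a logged error;
#' the run completes and reports the failures. Given identical inputs and
#' configuration the CSV outputs are byte-identical across reruns.
#'
#' @param manifest data.frame (or CSV path) with columns `field_path`,
#'   `animal_id`, `group`, `field_index`, `assay`.
#' @param config A [RunConfig-class].
#' @param outputDir Output directory (created if missing).
#' @param behavior Optional intake table ([BehaviorCohort-class],
#'   data.frame or CSV path).
#' @return Invisibly, a list: `summaries` (animal-level data.frame),
#'   `status` (per-field data.frame), `nFailed`, and `outputs` (paths).
#' @export
runBatch <- function(manifest, config, outputDir, behavior = NULL) {
  stopifnot(is(config, "RunConfig"))
  validObject(config)
  if (is.character(manifest)) manifest <- read.csv(manifest,
                                                   stringsAsFactors = FALSE)
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  cfgPath <- file.path(outputDir, "config.yaml")
  yaml::write_yaml(configToList(config), cfgPath)

  status <- data.frame(field_id = character(0), ok = logical(0),
                       message = character(0), seconds = numeric(0))
  perAnimal <- list()
  if (nrow(manifest) == 0)
    warning("empty manifest: producing empty outputs")

  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    fieldId <- sprintf("%s_f%02d", row$animal_id, as.integer(row$field_index))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      field <- if (is(row$field_path[[1]], "MultiplexField"))
        row$field_path[[1]] else
        readField(row$field_path, animalId = row$animal_id,
                  fieldIndex = row$field_index, assay = row$assay)
      out <- processField(field, config, fieldId)
      writeSpotsCsv(out$spots,
                    file.path(outputDir, paste0(fieldId, "_spots.csv")),
                    fieldId)
      writeCellCountsCsv(out$counts,
                         file.path(outputDir,
                                   paste0(fieldId, "_cellcounts.csv")))
      writeLabelMap(out$segmentation,
                    file.path(outputDir, paste0(fieldId, "_labels.tif")))
      out
    }, error = function(e) e)
    secs <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      status <- rbind(status, data.frame(field_id = fieldId, ok = FALSE,
                                         message = conditionMessage(res),
                                         seconds = secs))
    } else {
      status <- rbind(status, data.frame(field_id = fieldId, ok = TRUE,
                                         message = "", seconds = secs))
      key <- paste(row$animal_id, row$assay, sep = "|")
      perAnimal[[key]] <- c(perAnimal[[key]], list(res$counts))
    }
  }

  ## animal-level aggregation
  summaries <- NULL
  if (length(perAnimal)) {
    parts <- lapply(names(perAnimal), function(key) {
      kv <- strsplit(key, "|", fixed = TRUE)[[1]]
      mm <- config@markerMaps[[kv[2]]] %||% defaultMarkerMap("A")
      pth <- config@positivityThresholds[
        names(config@positivityThresholds) %in% unname(mm)]
      s <- aggregateAnimal(perAnimal[[key]], kv[1], mm, pth)
      s$assay <- kv[2]
      grp <- manifest$group[manifest$animal_id == kv[1]][1]
      s$group <- if (is.null(grp)) NA_character_ else grp
      s
    })
    ## per assay the percentage columns differ; bind within assay
    summaries <- do.call(rbind, parts[order(vapply(parts, function(p)
      paste(p$assay, p$animal_id), character(1)))])
    write.csv(summaries, file.path(outputDir, "animal_summaries.csv"),
              row.names = FALSE)
  }

  ## behavioural statistics
  if (!is.null(behavior) && !is.null(summaries)) {
    if (is.character(behavior)) behavior <- readBehaviorCsv(behavior)
    if (is(behavior, "BehaviorCohort")) behavior <- intakeTable(behavior)
    phen <- phenotypeQuartiles(behavior)
    write.csv(phen, file.path(outputDir, "phenotypes.csv"),
              row.names = FALSE)
    metrics <- summaries[, c("animal_id", "total_ch1", "total_ch2",
                             "total_ch4")]
    cm <- spearmanBH(behavior, metrics)
    write.csv(correlationTable(cm),
              file.path(outputDir, "correlation_matrix.csv"),
              row.names = FALSE)
    correlationHeatmap(cm, file.path(outputDir, "correlation_matrix.png"))
    grp <- phen$phenotype[match(summaries$animal_id, phen$animal_id)]
    kws <- lapply(c("total_ch1", "total_ch2", "total_ch4"), function(mcol) {
      vals <- split(summaries[[mcol]], grp)
      vals <- vals[lengths(vals) > 0]
      if (length(vals) < 2) return(NULL)
      kw <- kruskalWallis(vals)
      data.frame(metric = mcol, H = kw$H, df = kw$df, p.value = kw$p.value)
    })
    kws <- do.call(rbind, kws)
    if (!is.null(kws))
      write.csv(kws, file.path(outputDir, "kruskal_wallis.csv"),
                row.names = FALSE)
  }

  log <- list(package = "puncta",
              version = as.character(utils::packageVersion("puncta")),
              config_file = "config.yaml",
              config_md5 = unname(tools::md5sum(cfgPath)),
              n_fields = nrow(manifest),
              n_failed = sum(!status$ok),
              fields = status)
  jsonlite::write_json(log, file.path(outputDir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(summaries = summaries, status = status,
                 nFailed = sum(!status$ok), outputDir = outputDir))
}

## Normalise a matrix to [0,1] for display.
norm01 <- function(m) {
  r <- range(m)
  if (diff(r) == 0) return(m * 0)
  (m - r[1]) / diff(r)
}

#' Render a threshold-tuning overlay for one sample field
#'
#' Draws detected spots (red crosses) and nucleus outlines (green) over
#' each channel so that per-channel thresholds can be judged on a sample
#' image before freezing them for the batch. Never mutates any batch
#' configuration.
#'
#' @param field A [MultiplexField-class].
#' @param config A [RunConfig-class] holding the candidate parameters.
#' @param path Output PNG (four panels: channels 1, 2, 4, DAPI).
#' @return Invisibly, a list with per-channel spot counts and the nucleus
#'   count.
#' @export
tunePreview <- function(field, config, path) {
  out <- processField(field, config, "preview")
  sp <- spots(out$spots)
  seg <- labelMap(out$segmentation)
  h <- dim(field@data)[1]; w <- dim(field@data)[2]
  outline <- seg > 0 & maxFilter3(matrix(as.numeric(seg == 0), h, w)) > 0
  panels <- c(1L, 2L, 4L, 3L)
  rgb <- array(0, dim = c(h, w * 4, 3))
  for (p in seq_along(panels)) {
    ch <- panels[p]
    g <- norm01(channelImage(field, ch))
    cols <- (p - 1) * w + seq_len(w)
    for (k in 1:3) rgb[, cols, k] <- g
    ## nucleus outlines in green
    rgb[, cols, 1][outline] <- 0
    rgb[, cols, 2][outline] <- 1
    rgb[, cols, 3][outline] <- 0
    if (ch != 3L) {
      pts <- sp[sp$channel == ch, , drop = FALSE]
      for (j in seq_len(nrow(pts))) {
        ys <- pmax(1, pmin(h, pts$y[j] + (-2:2)))
        xs <- pmax(1, pmin(w, pts$x[j] + (-2:2)))
        cx <- (p - 1) * w + pts$x[j]
        rgb[ys, (p - 1) * w + pmax(1, pmin(w, pts$x[j])), 1] <- 1
        rgb[pts$y[j], (p - 1) * w + xs, 1] <- 1
        rgb[ys, cx, 2:3] <- 0
        rgb[pts$y[j], (p - 1) * w + xs, 2:3] <- 0
      }
    }
  }
  png::writePNG(rgb, path)
  counts <- table(factor(sp$channel, levels = c(1, 2, 4)))
  invisible(list(spotCounts = setNames(as.integer(counts),
                                       c("ch1", "ch2", "ch4")),
                 nNuclei = nrow(nucleusTable(out$segmentation)),
                 path = path))
}

#' Render a correlation matrix heat map
#'
#' Cells show Spearman r (blue negative, red positive); BH-significant
#' cells are annotated with their r value and a box.
#'
#' @param cm A [CorrelationMatrix-class].
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
correlationHeatmap <- function(cm, path) {
  r <- cm@r
  png(path, width = 220 + 46 * ncol(r), height = 130 + 22 * nrow(r))
  on.exit(dev.off())
  pal <- colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  graphics::par(mar = c(7, 7, 2, 1))
  graphics::image(seq_len(ncol(r)), seq_len(nrow(r)), t(r)[, rev(seq_len(nrow(r))), drop = FALSE],
                  zlim = c(-1, 1), col = pal, axes = FALSE, xlab = "",
                  ylab = "")
  graphics::axis(1, at = seq_len(ncol(r)), labels = colnames(r), las = 2,
                 cex.axis = 0.8)
  graphics::axis(2, at = seq_len(nrow(r)), labels = rev(rownames(r)),
                 las = 1, cex.axis = 0.8)
  for (i in seq_len(nrow(r))) for (j in seq_len(ncol(r))) {
    if (isTRUE(cm@sig[i, j])) {
      graphics::text(j, nrow(r) + 1 - i, sprintf("%.2f", r[i, j]),
                     cex = 0.7)
      graphics::rect(j - 0.5, nrow(r) + 0.5 - i, j + 0.5,
                     nrow(r) + 1.5 - i, border = "black", lwd = 1.5)
    }
  }
  graphics::box()
  invisible(path)
}
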