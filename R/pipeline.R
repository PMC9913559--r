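#' Read nodule annotations from XML
#'
#' Parses a minimal annotation dialect modeled on the public thoracic CT
#' archives: a root element containing one `<reader>` per radiologist,
#' each with `<nodule>` children carrying a center, a diameter in mm, a
#' 1-5 malignancy grade and a solidity flag (see
#' `inst/extdata/example_annotations.xml` for the schema in use). When
#' several readers annotated the same exam, only the reader that
#' identified the most lesions is kept, which avoids double-counting
#' the same physical nodule. Records with a missing or out-of-range
#' malignancy grade are skipped with a warning.
#'
#' @param path path to an XML file (or an XML string).
#' @return data frame with columns `nodule_id`, `center_z`, `center_y`,
#'   `center_x`, `diameter_mm`, `malignancy`, `solid`, `reader_id`.
#' @export
read_annotations <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stopf("malformed XML: %s", conditionMessage(e)))
  readers <- xml2::xml_find_all(doc, ".//reader")
  empty <- data.frame(nodule_id = character(), center_z = numeric(),
                      center_y = numeric(), center_x = numeric(),
                      diameter_mm = numeric(), malignancy = integer(),
                      solid = logical(), reader_id = character())
  if (!length(readers)) return(empty)
  counts <- vapply(readers, function(r)
    length(xml2::xml_find_all(r, "./nodule")), integer(1L))
  best <- readers[[which.max(counts)]]  # ties: first reader in the file
  reader_id <- xml2::xml_attr(best, "id")
  nodules <- xml2::xml_find_all(best, "./nodule")
  if (!length(nodules)) return(empty)
  rows <- lapply(nodules, function(nd) {
    txt <- function(tag) xml2::xml_text(xml2::xml_find_first(nd, paste0("./", tag)))
    ctr <- xml2::xml_find_first(nd, "./center")
    grade <- suppressWarnings(as.integer(txt("malignancy")))
    id <- xml2::xml_attr(nd, "id")
    if (is.na(grade) || !grade %in% 1:5) {
      warnf("nodule '%s': missing or invalid malignancy grade; skipped", id)
      return(NULL)
    }
    data.frame(nodule_id = id,
               center_z = as.numeric(xml2::xml_attr(ctr, "z")),
               center_y = as.numeric(xml2::xml_attr(ctr, "y")),
               center_x = as.numeric(xml2::xml_attr(ctr, "x")),
               diameter_mm = as.numeric(txt("diameter_mm")),
               malignancy = grade,
               solid = tolower(txt("solid")) %in% c("true", "1", "yes"),
               reader_id = reader_id)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}

#' Pipeline configuration
#'
#' One flat list holding every stage's settings plus the global seed.
#' Serialized as sorted `key = value` lines, so serialize-parse-
#' serialize is byte-identical.
#'
#' @param box_size nodule box edge (and shape-matrix side; `n_angles`
#'   must equal it).
#' @param n_angles radial scan angles per slice.
#' @param window_width,window_level HU window.
#' @param epsilon Douglas-Peucker tolerance in pixels; `simplify`
#'   toggles simplification before scanning.
#' @param min_area minimum ROI area in pixels.
#' @param normalize shape-matrix normalization mode.
#' @param depth,base_filters,epochs,batch_size,lr network settings.
#' @param n_folds,k_neighbors protocol settings.
#' @param n_benign,n_malignant synthetic class counts.
#' @param amplitude_benign,amplitude_malignant,texture_noise_sd
#'   generator settings.
#' @param seed global seed.
#' @return an object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(box_size = 32L, n_angles = box_size,
                            window_width = 1600, window_level = -600,
                            epsilon = 0.8, simplify = TRUE, min_area = 9L,
                            normalize = "per_nodule_max",
                            depth = 3L, base_filters = 8L, epochs = 30L,
                            batch_size = 4L, lr = 5e-4,
                            n_folds = 10L, k_neighbors = 5L,
                            n_benign = 50L, n_malignant = 50L,
                            amplitude_benign = 0.05,
                            amplitude_malignant = 0.35,
                            texture_noise_sd = 15, seed = 0L) {
  cfg <- list(box_size = as.integer(box_size), n_angles = as.integer(n_angles),
              window_width = window_width, window_level = window_level,
              epsilon = epsilon, simplify = isTRUE(simplify),
              min_area = as.integer(min_area), normalize = normalize,
              depth = as.integer(depth), base_filters = as.integer(base_filters),
              epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              lr = lr, n_folds = as.integer(n_folds),
              k_neighbors = as.integer(k_neighbors),
              n_benign = as.integer(n_benign),
              n_malignant = as.integer(n_malignant),
              amplitude_benign = amplitude_benign,
              amplitude_malignant = amplitude_malignant,
              texture_noise_sd = texture_noise_sd, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
validate_config <- function(cfg) {
  if (cfg$n_angles != cfg$box_size)
    stopf("n_angles (%d) must equal box_size (%d) for a square shape matrix",
          cfg$n_angles, cfg$box_size)
  if (cfg$box_size %% 2L^cfg$depth != 0L)
    stopf("box_size %d is not divisible by 2^depth = %d",
          cfg$box_size, 2L^cfg$depth)
  if (cfg$epsilon <= 0) stopf("epsilon must be > 0")
  invisible(cfg)
}

#' Read / write a pipeline configuration file
#'
#' Flat `key = value` text; unknown keys are rejected, values are
#' coerced to the types of [pipeline_config()] defaults.
#'
#' @param path file path.
#' @return `read_config` returns a `pipeline_config`; `write_config`
#'   the path, invisibly.
#' @export
read_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stopf("cannot parse config line: '%s'", lines[bad][1L])
  keys <- vapply(kv, `[[`, character(1L), 1L)
  vals <- vapply(kv, `[[`, character(1L), 2L)
  defaults <- pipeline_config()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown)) stopf("unknown config key '%s'", unknown[1L])
  args <- lapply(setNames(seq_along(keys), keys), function(i) {
    proto <- defaults[[keys[i]]]
    if (is.logical(proto)) as.logical(vals[i])
    else if (is.integer(proto)) as.integer(vals[i])
    else if (is.numeric(proto)) as.numeric(vals[i])
    else vals[i]
  })
  do.call(pipeline_config, args)
}

#' @rdname read_config
#' @param cfg a [pipeline_config()].
#' @export
write_config <- function(cfg, path) {
  keys <- sort(names(cfg))
  fmt <- vapply(keys, function(k) {
    v <- cfg[[k]]
    sprintf("%s = %s", k,
            if (is.logical(v)) tolower(as.character(v))
            else format(v, digits = 15, scientific = FALSE))
  }, character(1L))
  writeLines(fmt, path)
  invisible(path)
}

#' Run the full pipeline on synthetic data
#'
#' Generates the configured dataset, runs windowless preprocessing on
#' each already-gray box (binarize, trace, simplify, radial scan),
#' builds the joint tensors, makes stratified folds, cross-validates
#' with in-fold SMOTE and writes per-fold and pooled metrics, the fold
#' plan, the manifest and a structured log (stage, parameters, output
#' digests) to `out_dir`. Rerunning with an identical configuration
#' reproduces every artifact.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return the [cross_validate()] result, invisibly.
#' @export
run_pipeline <- function(cfg, out_dir) {
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "pipeline.log")
  cat(sprintf("[config] %s\n",
              paste(sprintf("%s=%s", names(cfg), vapply(cfg, format, "")),
                    collapse = " ")), file = logf)
  log_stage <- function(stage, ...) {
    cat(sprintf("[%s] %s\n", stage, sprintf(...)), file = logf, append = TRUE)
  }
  run_stage <- function(stage, sample_id, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed on %s: %s", stage, sample_id, conditionMessage(e)))
  }
  scfg <- synth_config(box_size = cfg$box_size,
                       amplitude_benign = cfg$amplitude_benign,
                       amplitude_malignant = cfg$amplitude_malignant,
                       texture_noise_sd = cfg$texture_noise_sd,
                       seed = cfg$seed)
  ds <- run_stage("synth", "dataset",
                  gen_dataset(scfg, cfg$n_benign, cfg$n_malignant))
  write.csv(ds$manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  log_stage("synth", "%d boxes; manifest digest %s", nrow(ds$manifest),
            unname(tools::md5sum(file.path(out_dir, "manifest.csv"))))
  rcfg <- radial_config(cfg$n_angles, normalize = cfg$normalize)
  samples <- lapply(seq_along(ds$boxes), function(i)
    run_stage("series", ds$manifest$id[i],
              assemble_input(ds$boxes[[i]],
                             nodule_shape_matrix(ds$boxes[[i]], rcfg,
                                                 min_area = cfg$min_area,
                                                 simplify = cfg$simplify,
                                                 epsilon = cfg$epsilon))))
  log_stage("series", "%d joint tensors of extent %s", length(samples),
            paste(dim(samples[[1L]]$tensor)[-1L], collapse = "x"))
  labels <- ds$manifest$label
  plan <- run_stage("folds", "dataset",
                    make_folds(labels, cfg$n_folds, cfg$seed))
  ucfg <- unet_config(depth = cfg$depth, base_filters = cfg$base_filters,
                      lr = cfg$lr, epochs = cfg$epochs,
                      batch_size = cfg$batch_size, seed = cfg$seed)
  res <- run_stage("cv", "dataset",
                   cross_validate(samples, ucfg, plan,
                                  smote_config(cfg$k_neighbors, cfg$seed)))
  fold_tab <- data.frame(
    fold = seq_len(plan$n_folds),
    recall = vapply(res$per_fold, `[[`, numeric(1L), "recall"),
    precision = vapply(res$per_fold, `[[`, numeric(1L), "precision"),
    accuracy = vapply(res$per_fold, `[[`, numeric(1L), "accuracy"),
    f1 = vapply(res$per_fold, `[[`, numeric(1L), "f1"),
    n_synthetic = res$n_synthetic)
  write.csv(fold_tab, file.path(out_dir, "metrics_folds.csv"), row.names = FALSE)
  pooled <- res$pooled
  write.csv(data.frame(recall = pooled$recall, precision = pooled$precision,
                       accuracy = pooled$accuracy, f1 = pooled$f1,
                       auc = res$auc),
            file.path(out_dir, "metrics_pooled.csv"), row.names = FALSE)
  write_config(cfg, file.path(out_dir, "config.txt"))
  log_stage("cv", "pooled accuracy %.4f; metrics digest %s", pooled$accuracy,
            unname(tools::md5sum(file.path(out_dir, "metrics_pooled.csv"))))
  invisible(res)
}
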