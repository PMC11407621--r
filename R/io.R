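#' Read a fluorescence stack from disk
#'
#' Reads a multi-page TIFF (values returned as stored, promoted to double)
#' or a native `.rds` array. Single images are promoted to one-frame stacks.
#'
#' @param path file path (`.tif`, `.tiff`, or `.rds`).
#' @return H x W x T numeric array.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                      error = function(e) stopf("cannot read TIFF '%s': %s",
                                                path, conditionMessage(e)))
    if (is.matrix(pages)) pages <- list(pages)
    dims <- lapply(pages, dim)
    if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
      stopf("TIFF pages of '%s' have inconsistent dimensions", path)
    }
    d <- dims[[1L]]
    if (length(d) != 2L) stopf("'%s' is not a grayscale stack", path)
    arr <- array(unlist(pages), c(d[1L], d[2L], length(pages)))
    storage.mode(arr) <- "double"
    arr
  } else if (ext == "rds") {
    as_stack(readRDS(path), path)
  } else {
    stopf("unsupported stack format '%s' (use .tif/.tiff or .rds)", ext)
  }
}

#' Write a fluorescence stack to disk
#'
#' TIFF output is 16-bit; values must lie in \[0, 65535\] and are stored as
#' integers, so integer-valued stacks round-trip exactly through
#' [read_stack()]. `.rds` output stores the array as-is.
#'
#' @param stack H x W x T numeric array.
#' @param path output path (`.tif`, `.tiff`, or `.rds`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stack <- as_stack(stack)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (min(stack) < 0 || max(stack) > 65535) {
      stopf("TIFF output requires values in [0, 65535]; rescale first")
    }
    pages <- lapply(seq_len(dim(stack)[3L]),
                    function(t) round(stack[, , t]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else if (ext == "rds") {
    saveRDS(stack, path)
  } else {
    stopf("unsupported stack format '%s' (use .tif/.tiff or .rds)", ext)
  }
  invisible(path)
}

#' Write simulator ground truth
#'
#' Writes `ground_truth.json` (neurons, patterns, seed, config scalars) and
#' `spikes.csv` (neurons x frames spike counts) into a directory.
#'
#' @param dataset a `sim_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- dataset$config
  cfg$pattern_params <- NULL
  jsonlite::write_json(
    list(neurons = dataset$neurons, seed = dataset$seed,
         config = cfg[!vapply(cfg, is.null, logical(1))],
         pattern_params = dataset$config$pattern_params),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  write.csv(dataset$spikes, file.path(dir, "spikes.csv"), row.names = TRUE)
  invisible(dir)
}

#' Write an ROI mask and table
#'
#' Writes the binary mask as `mask.png` and `mask.csv` (plain 0/1 matrix)
#' and the labeled ROI table as `rois.csv`.
#'
#' @param rois a `roi_mask` or `roi_set`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_rois <- function(rois, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rset <- if (inherits(rois, "roi_set")) rois else label_rois(rois)
  mask <- (rset$labels > 0L) + 0
  png::writePNG(mask, file.path(dir, "mask.png"))
  write.table(mask, file.path(dir, "mask.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  write.csv(rset$table, file.path(dir, "rois.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write ROI traces in long format
#'
#' @param traces T x K trace matrix (columns named by ROI label).
#' @param path output CSV path; columns `frame`, `roi_label`, `dff_percent`.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  labs <- colnames(traces) %||% as.character(seq_len(ncol(traces)))
  long <- data.frame(
    frame = rep(seq_len(nrow(traces)), times = ncol(traces)),
    roi_label = rep(labs, each = nrow(traces)),
    dff_percent = as.vector(traces)
  )
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read ROI traces written by [write_traces()]
#'
#' @param path CSV path.
#' @return T x K matrix with ROI labels as column names.
#' @export
read_traces <- function(path) {
  long <- read.csv(path)
  need <- c("frame", "roi_label", "dff_percent")
  if (!all(need %in% names(long))) {
    stopf("'%s' must have columns %s", path, paste(need, collapse = ", "))
  }
  labs <- unique(long$roi_label)
  out <- vapply(labs, function(l) {
    sub <- long[long$roi_label == l, ]
    sub$dff_percent[order(sub$frame)]
  }, numeric(max(long$frame)))
  out <- matrix(out, ncol = length(labs))
  colnames(out) <- labs
  out
}

#' Read a simulator or pipeline configuration file
#'
#' YAML or JSON files holding [sim_config()] / [pipeline_config()]
#' arguments. Unknown keys are rejected by the constructors.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stopf("unsupported config format '%s' (use YAML or JSON)", ext)
  }
}

#' Build a [sim_config()] from a configuration list
#'
#' @param lst named list of [sim_config()] arguments (e.g. from
#'   [read_config()]).
#' @return a `sim_config`.
#' @export
sim_config_from_list <- function(lst) {
  if (inherits(lst, "sim_config")) return(lst)
  known <- names(formals(sim_config))
  bad <- setdiff(names(lst), known)
  if (length(bad)) stopf("unknown sim_config field(s): %s",
                         paste(bad, collapse = ", "))
  if (!is.null(lst$pattern_params)) {
    lst$pattern_params <- as.data.frame(lst$pattern_params)
  }
  do.call(sim_config, lst)
}
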