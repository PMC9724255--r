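# On-disk formats. All files are UTF-8 text with header rows and '.'
# decimals: beta matrices as TSV (first column the probe id, remaining
# columns one per sample), manifests/annotations as CSV, chromatograms as
# two-column CSV with a JSON sidecar carrying run metadata, panels as JSON,
# rates as TSV. Reads validate structure and fail with file context.

#' Write / read a beta-value matrix as TSV
#'
#' @param beta Numeric matrix, probes x samples.
#' @param path File path.
#' @return `read_beta_matrix()` returns the matrix with probe rownames.
#' @export
write_beta_matrix <- function(beta, path) {
  dt <- data.table::data.table(probe_id = rownames(beta), beta)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_beta_matrix
#' @export
read_beta_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (names(dt)[1] != "probe_id") {
    stop_config("%s: first column must be 'probe_id'", path)
  }
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  if (anyDuplicated(rownames(m))) stop_config("%s: duplicate probe ids", path)
  bad <- which(!is.na(m) & (m < 0 | m > 1))
  if (length(bad)) {
    stop_config("%s: beta value outside [0, 1] at cell %d", path, bad[1])
  }
  m
}

#' Write / read the probe manifest as CSV
#' @param manifest Data frame with `probe_id`, `chromosome`, `gene_symbol`,
#'   `gene_region`, `cpg_class`, `call_proportion`.
#' @param path File path.
#' @return `read_manifest()` returns the data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(chromosome = "character"))
  req <- c("probe_id", "chromosome", "call_proportion")
  miss <- setdiff(req, names(m))
  if (length(miss)) {
    stop_config("%s: manifest missing column(s): %s", path,
                paste(miss, collapse = ", "))
  }
  m
}

#' Write / read the sample annotation as CSV
#' @param annotation Data frame with `sample_id`, `group`, `cohort`,
#'   `ballooning`, `brunt_stage`.
#' @param path File path.
#' @return `read_annotation()` returns the data frame.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.csv(annotation, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  a <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "group"), names(a))
  if (length(miss)) {
    stop_config("%s: annotation missing column(s): %s", path,
                paste(miss, collapse = ", "))
  }
  a
}

#' Write / read a chromatogram as CSV plus JSON sidecar
#'
#' The CSV holds `time_min, absorbance`; the sidecar `<path>.json` records
#' `run_id`, `marker_id`, `role` and optionally `sample_id`.
#'
#' @param chrom A [chromatogram()].
#' @param path CSV file path.
#' @return `read_chromatogram()` returns a `chromatogram`.
#' @export
write_chromatogram <- function(chrom, path) {
  utils::write.csv(data.frame(time_min = chrom$time,
                              absorbance = chrom$absorbance),
                   path, row.names = FALSE)
  meta <- list(run_id = chrom$run_id, marker_id = chrom$marker_id,
               role = chrom$role)
  if (!is.null(chrom$sample_id)) meta$sample_id <- chrom$sample_id
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_chromatogram
#' @export
read_chromatogram <- function(path) {
  d <- utils::read.csv(path)
  miss <- setdiff(c("time_min", "absorbance"), names(d))
  if (length(miss)) {
    stop_config("%s: chromatogram missing column(s): %s", path,
                paste(miss, collapse = ", "))
  }
  if (any(diff(d$time_min) <= 0)) {
    stop_config("%s: time_min must be strictly increasing", path)
  }
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::fromJSON(sidecar) else
    list(run_id = "run1", marker_id = "marker1", role = "sample")
  ch <- chromatogram(d$time_min, d$absorbance, run_id = meta$run_id,
                     marker_id = meta$marker_id, role = meta$role)
  if (!is.null(meta$sample_id)) ch$sample_id <- meta$sample_id
  ch
}

#' Write / read quantified methylation rates as TSV
#' @param rates Data frame from [quantify_run()].
#' @param path File path.
#' @return `read_rates()` returns the data frame.
#' @export
write_rates <- function(rates, path) {
  utils::write.table(rates, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_rates
#' @export
read_rates <- function(path) {
  r <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "marker_id"), names(r))
  if (length(miss)) {
    stop_config("%s: rates missing column(s): %s", path,
                paste(miss, collapse = ", "))
  }
  r
}
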