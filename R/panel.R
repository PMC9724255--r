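#' Construct a marker panel
#'
#' A panel is the set of candidate marker CpG sites carried forward to
#' quantification: per marker a cutoff (beta units or percent, per the
#' measurement platform), a direction, the AUC against normal tissue and the
#' specificity against the non-cancer disease group.
#'
#' @param entries Data frame with columns `marker_id`, `cutoff`, `direction`
#'   (`"hyper"`/`"hypo"`), `auc`, `specificity` (against the disease control
#'   group; NA allowed for hand-written panels).
#' @param selection_params Optional list recording `auc_threshold` and
#'   `specificity_threshold`.
#' @return Object of class `marker_panel`.
#' @export
marker_panel <- function(entries, selection_params = NULL) {
  req <- c("marker_id", "cutoff", "direction")
  miss <- setdiff(req, names(entries))
  if (length(miss)) {
    stop_config("panel entries missing field(s): %s",
                paste(miss, collapse = ", "))
  }
  if (!all(entries$direction %in% c("hyper", "hypo"))) {
    stop_config("direction must be 'hyper' or 'hypo'")
  }
  for (opt in c("auc", "specificity", "sensitivity")) {
    if (is.null(entries[[opt]])) entries[[opt]] <- NA_real_
  }
  structure(list(entries = as.data.frame(entries),
                 selection_params = selection_params),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("Marker panel: %d marker(s)\n", nrow(x$entries)))
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Two-stage marker-panel selection
#'
#' Stage 1 keeps probes whose AUC for discriminating the case group
#' (default NASH-W) from normal tissue (NLT) strictly exceeds
#' `auc_threshold`, and fixes each survivor's Youden cutoff on that
#' comparison. Stage 2 keeps survivors whose specificity against the
#' disease control group (default NASH-O, treated as controls under the
#' stage-1 cutoff) is at least `specificity_threshold` — the gate that
#' selects markers usable for risk estimation within the disease population
#' rather than mere disease detection.
#'
#' @param trend_set Data frame with `probe_id` (e.g., output of
#'   [trend_inherited_set()]), or a character vector of probe ids.
#' @param beta Probes x samples matrix.
#' @param annotation Sample annotation (`sample_id`, `group`).
#' @param auc_threshold Strict lower bound on stage-1 AUC (default 0.95).
#' @param specificity_threshold Inclusive lower bound on stage-2
#'   specificity (default 0.85).
#' @param case_group,control_group,disease_control_group Group labels for
#'   the case, normal-control and disease-control comparisons.
#' @return A `marker_panel`; its `selection_params` also records the
#'   stage-1 probe set and hyper/hypo counts.
#' @export
select_panel <- function(trend_set, beta, annotation,
                         auc_threshold = 0.95, specificity_threshold = 0.85,
                         case_group = "NASH-W", control_group = "NLT",
                         disease_control_group = "NASH-O") {
  probe_ids <- if (is.data.frame(trend_set)) trend_set$probe_id else trend_set
  for (g in c(case_group, control_group, disease_control_group)) {
    if (!g %in% annotation$group) stop_config("group '%s' missing", g)
  }
  sel_cols <- function(g) {
    intersect(annotation$sample_id[annotation$group == g], colnames(beta))
  }
  cols_case <- sel_cols(case_group)
  cols_ctrl <- sel_cols(control_group)
  cols_dis <- sel_cols(disease_control_group)

  rows <- lapply(probe_ids, function(pid) {
    cs <- beta[pid, cols_case]; ct <- beta[pid, cols_ctrl]
    roc <- roc_auc(cs, ct)
    if (roc$auc <= auc_threshold) return(NULL)
    yc <- youden_cutoff(cs, ct, direction = roc$direction)
    spec_dis <- evaluate_criterion(
      c(cs, beta[pid, cols_dis]), yc$cutoff, roc$direction,
      c(rep(TRUE, length(cs)), rep(FALSE, length(cols_dis))))$specificity
    data.frame(marker_id = pid, cutoff = yc$cutoff,
               direction = roc$direction, auc = roc$auc,
               sensitivity = yc$sensitivity, specificity = spec_dis,
               stringsAsFactors = FALSE)
  })
  stage1 <- do.call(rbind, rows)
  if (is.null(stage1)) {
    stage1 <- data.frame(marker_id = character(0), cutoff = numeric(0),
                         direction = character(0), auc = numeric(0),
                         sensitivity = numeric(0), specificity = numeric(0))
  }
  keep <- stage1$specificity >= specificity_threshold
  panel <- marker_panel(stage1[keep, , drop = FALSE],
                        selection_params = list(
                          auc_threshold = auc_threshold,
                          specificity_threshold = specificity_threshold,
                          stage1_ids = stage1$marker_id,
                          n_stage1 = nrow(stage1),
                          n_hyper = sum(stage1$direction == "hyper"),
                          n_hypo = sum(stage1$direction == "hypo")))
  panel
}

#' Write / read a marker panel as JSON
#'
#' The on-disk form is an array of objects with fields `marker_id`,
#' `cutoff`, `direction`, `auc`, `specificity`; hand-written panels (e.g.,
#' encoding published cutoffs) are accepted. Missing required fields raise
#' a schema error naming the field.
#'
#' @param panel A `marker_panel`.
#' @param path File path.
#' @return `read_panel()` returns a `marker_panel`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "marker_panel"))
  jsonlite::write_json(panel$entries, path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  entries <- jsonlite::fromJSON(path)
  for (field in c("marker_id", "cutoff", "direction")) {
    if (is.null(entries[[field]])) {
      stop_config("panel JSON schema error: missing field '%s'", field)
    }
  }
  marker_panel(entries)
}
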