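# Readers and writers for the package's plain-text interchange formats:
# screening tables, secondary-structure annotations, dual-electrode
# measurement summaries, assay traces and amperograms (all CSV with a
# header row), plus YAML run configurations and JSON decisions.

#' Read a screening table from CSV
#'
#' Expected columns: `position`, `reads`, `r1_rate`, `r1_control_rate`,
#' `dmso_1..3`, `ht_1..3`, optionally `truth_label`.
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_screen_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("position", "r1_rate", "r1_control_rate",
            paste0("dmso_", 1:3), paste0("ht_", 1:3))
  check_that(all(need %in% names(tab)),
             paste("screen table is missing columns:",
                   paste(setdiff(need, names(tab)), collapse = ", ")))
  tab
}

#' Read a secondary-structure annotation from CSV
#'
#' Expected columns: `residue`, `ss_class` (loop/helix/sheet), optional
#' `interface` (logical).
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_ss_annotation <- function(path) {
  ss <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_that(all(c("residue", "ss_class") %in% names(ss)),
             "annotation needs `residue` and `ss_class` columns")
  if (!is.null(ss$interface)) ss$interface <- as.logical(ss$interface)
  ss
}

#' Read dual-electrode measurements from CSV
#'
#' Expected columns: `electrode_id`, `mean_uA`, `sd_uA`, `n`, optional
#' `glucose_mM_est` and `sample_id`. Electrode ids containing `"5e"` (case
#' insensitive) are taken as the engineered electrode, the others as wild
#' type; each sample must contribute exactly one of each.
#'
#' @param path CSV file path.
#' @return List of [dual_measurement()] objects, one per sample.
#' @export
read_dual_measurements <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_that(all(c("electrode_id", "mean_uA", "sd_uA", "n") %in% names(tab)),
             "dual-measurement CSV needs electrode_id, mean_uA, sd_uA, n")
  if (is.null(tab$sample_id)) tab$sample_id <- 1L
  lapply(split(tab, tab$sample_id), function(g) {
    is5e <- grepl("5e", g$electrode_id, ignore.case = TRUE)
    check_that(sum(is5e) == 1 && sum(!is5e) == 1,
               "each sample needs one engineered and one wild-type electrode row")
    a <- g[is5e, ]; b <- g[!is5e, ]
    est <- if (!is.null(g$glucose_mM_est)) a$glucose_mM_est else NULL
    dual_measurement(
      i_5e = electrode_summary(a$mean_uA, a$sd_uA, a$n),
      i_wt = electrode_summary(b$mean_uA, b$sd_uA, b$n),
      glucose_mM_est = est
    )
  })
}

#' Read an assay trace from CSV
#'
#' Expected columns: `time_s`, `absorbance`, optional `replicate_id`,
#' `condition_id`.
#'
#' @param path CSV file path.
#' @return `assay_trace`-compatible list.
#' @export
read_assay_trace <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_that(all(c("time_s", "absorbance") %in% names(tab)),
             "assay-trace CSV needs time_s and absorbance")
  check_that(all(diff(tab$time_s) > 0), "times must be strictly increasing")
  structure(list(times_s = tab$time_s, absorbance_600 = tab$absorbance,
                 condition = unique(tab$condition_id),
                 replicate_id = unique(tab$replicate_id)),
            class = "assay_trace")
}

#' Read an amperogram (with optional event sidecar) from CSV
#'
#' @param path CSV with `time_s`, `current_uA`.
#' @param events_path Optional sidecar CSV with `time_s`,
#'   `delta_glucose_mM`, `species`, `concentration_M`.
#' @param electrode `electrode_spec` to attach.
#' @return `amperogram` object.
#' @export
read_amperogram <- function(path, events_path = NULL,
                            electrode = electrode_spec()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_that(all(c("time_s", "current_uA") %in% names(tab)),
             "amperogram CSV needs time_s and current_uA")
  check_that(all(diff(tab$time_s) > 0), "times must be strictly increasing")
  events <- list()
  if (!is.null(events_path)) {
    ev <- utils::read.csv(events_path, stringsAsFactors = FALSE)
    events <- lapply(seq_len(nrow(ev)), function(i) {
      dose <- if (!is.na(ev$concentration_M[i]) && nzchar(ev$species[i]))
        ligand_dose(ev$species[i], ev$concentration_M[i], 0.01) else NULL
      injection_event(ev$time_s[i], ev$delta_glucose_mM[i], dose)
    })
  }
  structure(list(times_s = tab$time_s, current_uA = tab$current_uA,
                 events = events, electrode = electrode,
                 enzyme = NULL, i_ss_uA = NULL),
            class = "amperogram")
}

#' Serialise a decoder decision to JSON
#'
#' @param decision A `decision` from [classify_ratio()].
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
decision_to_json <- function(decision, path = NULL) {
  stopifnot(inherits(decision, "decision"))
  x <- unclass(decision)
  if (is.null(path)) return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
}

#' Read a YAML run configuration
#'
#' Reads a configuration with optional `enzymes:` entries (each a list of
#' [enzyme_params()] arguments) and optional `sim:` entries
#' ([sim_config()] arguments).
#'
#' @param path YAML file path.
#' @return List with `enzymes` (named list of `enzyme_params`) and `sim`
#'   (`sim_config` or `NULL`), plus any other top-level entries verbatim.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- cfg
  if (!is.null(cfg$enzymes)) {
    out$enzymes <- lapply(cfg$enzymes, function(e) {
      if (!is.null(e$selectivity)) e$selectivity <- unlist(e$selectivity)
      if (!is.null(e$ligand_range_M)) e$ligand_range_M <- unlist(e$ligand_range_M)
      do.call(enzyme_params, e)
    })
  }
  if (!is.null(cfg$sim)) out$sim <- do.call(sim_config, cfg$sim)
  out
}
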