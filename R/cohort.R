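#' Percent clinical improvement from baseline and follow-up scores
#'
#' All scales handled here (e.g. BFMDRS, UPDRS-III, Y-BOCS, YGTSS) are
#' severity scales — higher is worse — so improvement is the percent
#' *reduction* from pre-operative baseline to follow-up under stimulation:
#' `100 * (baseline - followup) / baseline`. Values may be negative
#' (worsening); nothing is clipped. Set `higher_is_better = TRUE` for scales
#' where an increase means improvement.
#'
#' @param baseline baseline score(s), strictly positive.
#' @param followup follow-up score(s).
#' @param higher_is_better flip the sign convention for gain-type scales.
#' @return percent improvement, vectorised over inputs.
#' @examples
#' percent_improvement(35, 14)   # 60
#' percent_improvement(26, 6)    # 76.9...
#' @export
percent_improvement <- function(baseline, followup, higher_is_better = FALSE) {
  if (any(!is.finite(baseline)) || any(baseline <= 0))
    stop("baseline scores must be finite and > 0")
  imp <- 100 * (baseline - followup) / baseline
  if (higher_is_better) -imp else imp
}

#' Patient record
#'
#' One patient: identifiers, scores, derived percent improvement, and one
#' E-field per implanted hemisphere (one or two).
#'
#' @param patient_id unique identifier.
#' @param disorder disorder tag (e.g. `"DYT"`, `"PD"`, `"TS"`, `"OCD"` or a
#'   synthetic label).
#' @param baseline,followup clinical scores (baseline > 0).
#' @param efields named list of [voxel_volume()]s keyed `"left"` / `"right"`
#'   (units `V_per_m`), or `NULL`.
#' @return object of class `patient_record`.
#' @export
patient_record <- function(patient_id, disorder, baseline, followup,
                           efields = NULL) {
  imp <- percent_improvement(baseline, followup)
  if (!is.null(efields)) {
    stopifnot(is.list(efields), length(efields) %in% 1:2,
              all(names(efields) %in% c("left", "right")))
  }
  structure(list(patient_id = as.character(patient_id),
                 disorder = as.character(disorder),
                 baseline = baseline, followup = followup,
                 improvement_pct = imp, efields = efields),
            class = "patient_record")
}

#' Cohort of patients sharing one disorder
#'
#' @param records list of [patient_record()]s with unique ids and a single
#'   shared disorder tag.
#' @param metadata free-form list.
#' @return object of class `dbs_cohort`.
#' @export
cohort <- function(records, metadata = list()) {
  stopifnot(is.list(records), length(records) >= 1L,
            all(vapply(records, inherits, TRUE, "patient_record")))
  ids <- vapply(records, `[[`, "", "patient_id")
  if (anyDuplicated(ids))
    stop("duplicate patient_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  dis <- unique(vapply(records, `[[`, "", "disorder"))
  if (length(dis) != 1L)
    stop("cohort mixes disorders: ", paste(dis, collapse = ", "))
  structure(list(records = records, disorder = dis, metadata = metadata),
            class = "dbs_cohort")
}

#' @export
print.dbs_cohort <- function(x, ...) {
  imp <- improvements(x)
  cat(sprintf("<dbs_cohort> %s, n = %d, improvement %.1f +/- %.1f%%\n",
              x$disorder, length(x$records), mean(imp), stats::sd(imp)))
  invisible(x)
}

#' @export
length.dbs_cohort <- function(x) length(x$records)

#' Per-patient improvements of a cohort
#' @param x a [cohort()].
#' @return named numeric vector, one percent improvement per patient.
#' @export
improvements <- function(x) {
  stopifnot(inherits(x, "dbs_cohort"))
  v <- vapply(x$records, `[[`, 0, "improvement_pct")
  names(v) <- vapply(x$records, `[[`, "", "patient_id")
  v
}

#' Subset a cohort by record index
#' @param x a [cohort()].
#' @param idx integer or logical index.
#' @return a [cohort()].
#' @export
subset_cohort <- function(x, idx) {
  cohort(x$records[idx], x$metadata)
}

#' Pool E-fields of a cohort into one observation list
#'
#' Returns every hemisphere's E-field as one observation paired with its
#' patient's improvement — the observation unit of group-level mapping.
#'
#' @param x a [cohort()].
#' @return list with `volumes` (list of [voxel_volume()]), `improvement`
#'   (numeric), `patient_id`, `hemisphere` (character vectors).
#' @export
pooled_efields <- function(x) {
  stopifnot(inherits(x, "dbs_cohort"))
  vols <- list(); imp <- numeric(); pid <- character(); hemi <- character()
  for (rec in x$records) {
    if (is.null(rec$efields)) next
    for (h in names(rec$efields)) {
      vols[[length(vols) + 1L]] <- rec$efields[[h]]
      imp <- c(imp, rec$improvement_pct)
      pid <- c(pid, rec$patient_id)
      hemi <- c(hemi, h)
    }
  }
  list(volumes = vols, improvement = imp, patient_id = pid, hemisphere = hemi)
}

#' Load a cohort from a CSV table and an E-field manifest
#'
#' The cohort table needs columns `patient_id, disorder, baseline, followup`
#' and may carry `improvement_pct`; improvement is always recomputed from the
#' scores and cross-checked against the provided column (a discrepancy above
#' 0.5 percentage points warns). The manifest maps `patient_id, hemisphere`
#' to an `efield_path` readable by [load_volume()].
#'
#' @param table_path CSV cohort table.
#' @param manifest_path optional CSV manifest; `NULL` loads scores only.
#' @return a [cohort()].
#' @export
load_cohort <- function(table_path, manifest_path = NULL) {
  tab <- utils::read.csv(table_path, stringsAsFactors = FALSE)
  need <- c("patient_id", "disorder", "baseline", "followup")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("cohort table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$patient_id))
    stop("duplicate patient_id(s) in cohort table: ",
         paste(unique(tab$patient_id[duplicated(tab$patient_id)]),
               collapse = ", "))
  bad <- tab$patient_id[!is.finite(tab$baseline) | tab$baseline <= 0]
  if (length(bad))
    stop("non-positive baseline for patient(s): ", paste(bad, collapse = ", "))
  manifest <- NULL
  if (!is.null(manifest_path)) {
    manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
    stopifnot(all(c("patient_id", "hemisphere", "efield_path") %in%
                    names(manifest)))
    gone <- manifest$efield_path[!file.exists(manifest$efield_path)]
    if (length(gone))
      stop("missing E-field file(s): ", paste(gone, collapse = ", "))
  }
  tab <- tab[order(tab$patient_id), , drop = FALSE]
  records <- lapply(seq_len(nrow(tab)), function(r) {
    row <- tab[r, ]
    ef <- NULL
    if (!is.null(manifest)) {
      rows <- manifest[manifest$patient_id == row$patient_id, , drop = FALSE]
      if (nrow(rows) > 0) {
        rows <- rows[order(rows$hemisphere), , drop = FALSE]
        ef <- lapply(rows$efield_path, load_volume)
        names(ef) <- rows$hemisphere
      }
    }
    rec <- patient_record(row$patient_id, row$disorder, row$baseline,
                          row$followup, ef)
    if ("improvement_pct" %in% names(row) && is.finite(row$improvement_pct) &&
        abs(row$improvement_pct - rec$improvement_pct) > 0.5)
      warning(sprintf(
        "patient %s: provided improvement %.2f%% differs from recomputed %.2f%%",
        rec$patient_id, row$improvement_pct, rec$improvement_pct))
    rec
  })
  cohort(records)
}
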