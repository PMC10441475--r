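# CSV/JSON dialects shared by all modules. Comma-separated, dot decimal,
# header required, UTF-8. Internal units are SI (M, s, RU); files carry the
# display units in their column names (conc_nM).

#' Write a sensorgram to CSV
#'
#' Columns: `time_s`, `response_RU`, `conc_nM`, `phase`.
#'
#' @param sg A `sensorgram`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sensorgram_csv <- function(sg, path) {
  stopifnot(inherits(sg, "sensorgram"))
  d <- sg$data
  out <- data.frame(time_s = d$time_s, response_RU = d$response_RU,
                    conc_nM = d$conc_M * 1e9, phase = d$phase)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sensorgram from CSV
#'
#' Expects the dialect written by [write_sensorgram_csv()]; a schedule (or
#' its JSON path) must be supplied since the CSV stores only the realized
#' concentration track. Validates monotone time and finite responses, and
#' checks the concentration track against the schedule.
#'
#' @param path CSV path.
#' @param schedule An `injection_schedule`, or path to a schedule JSON.
#' @return A `sensorgram`.
#' @export
read_sensorgram_csv <- function(path, schedule) {
  if (is.character(schedule)) schedule <- read_schedule_json(schedule)
  stopifnot(inherits(schedule, "injection_schedule"))
  d <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("time_s", "response_RU", "conc_nM")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), " in ", path)
  if (any(diff(d$time_s) <= 0)) {
    i <- which(diff(d$time_s) <= 0)[1]
    stop("non-monotone time at row ", i + 1, " in ", path)
  }
  if (any(!is.finite(d$response_RU)))
    stop("non-finite response at row ",
         which(!is.finite(d$response_RU))[1], " in ", path)
  expected <- conc_at_times(schedule, d$time_s) * 1e9
  if (max(abs(d$conc_nM - expected)) > 1e-6 * max(expected, 1))
    stop("concentration track does not match the schedule in ", path)
  new_sensorgram(d$time_s, d$response_RU, schedule)
}

#' Write a titration curve to CSV
#'
#' Columns: `conc_nM`, `signal`, `replicate`.
#'
#' @param curve A `titration_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(curve, path) {
  stopifnot(inherits(curve, "titration_curve"))
  d <- curve$data
  out <- data.frame(conc_nM = d$conc_M * 1e9, signal = d$signal,
                    replicate = d$replicate)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a titration curve from CSV
#'
#' @param path CSV path with columns `conc_nM`, `signal` and optionally
#'   `replicate`. Non-positive concentrations are rejected with their row
#'   index.
#' @return A `titration_curve`.
#' @export
read_titration_csv <- function(path) {
  d <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("conc_nM", "signal")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), " in ", path)
  bad <- which(!is.finite(d$conc_nM) | d$conc_nM <= 0)
  if (length(bad))
    stop("non-positive concentration at row ", bad[1], " in ", path)
  rep_id <- if ("replicate" %in% names(d)) d$replicate else NULL
  titration_curve(d$conc_nM * 1e-9, d$signal, rep_id)
}

#' Write a trajectory to CSV
#'
#' Columns: `time`, coordinates (`x`, `y`, `z` as applicable),
#' `segment_id`.
#'
#' @param traj A `trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  d <- ncol(traj$coords)
  out <- data.frame(time = traj$times)
  cn <- c("x", "y", "z")[seq_len(d)]
  for (i in seq_len(d)) out[[cn[i]]] <- traj$coords[, i]
  out$segment_id <- traj$segments
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trajectory from CSV
#'
#' @param path CSV path in the [write_trajectory_csv()] dialect.
#' @return A `trajectory`.
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!"time" %in% names(d)) stop("missing column: time in ", path)
  cn <- intersect(c("x", "y", "z"), names(d))
  if (!length(cn)) stop("no coordinate columns (x/y/z) in ", path)
  if (any(diff(d$time) <= 0))
    stop("non-monotone time at row ", which(diff(d$time) <= 0)[1] + 1)
  new_trajectory(times = d$time, coords = as.matrix(d[cn]), stride = NA,
                 timestep = NA,
                 segments = if ("segment_id" %in% names(d)) d$segment_id
                 else NULL)
}

#' Write a trajectory in an XYZ-like text dialect
#'
#' One block per frame: point count, a comment line with the time, then
#' one `P x y z` line (missing dimensions padded with 0) — readable by
#' standard molecular viewers.
#'
#' @param traj A `trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  co <- cbind(traj$coords,
              matrix(0, nrow(traj$coords), 3 - ncol(traj$coords)))
  lines <- character(3 * nrow(co))
  lines[seq(1, length(lines), 3)] <- "1"
  lines[seq(2, length(lines), 3)] <- sprintf("t = %.6f", traj$times)
  lines[seq(3, length(lines), 3)] <-
    sprintf("P %.6f %.6f %.6f", co[, 1], co[, 2], co[, 3])
  writeLines(lines, path)
  invisible(path)
}

#' Write an injection schedule as JSON
#'
#' Concentrations are stored in nM (the display unit).
#'
#' @param schedule An `injection_schedule`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule_json <- function(schedule, path) {
  stopifnot(inherits(schedule, "injection_schedule"))
  jsonlite::write_json(
    list(concentrations_nM = schedule$concentrations_M * 1e9,
         association_s = schedule$association_s,
         inter_dissociation_s = schedule$inter_dissociation_s,
         final_dissociation_s = schedule$final_dissociation_s,
         sample_rate = schedule$sample_rate),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an injection schedule from JSON
#'
#' @param path JSON path in the [write_schedule_json()] dialect.
#' @return An `injection_schedule` (concentrations normalized to M).
#' @export
read_schedule_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("concentrations_nM", "association_s")
  miss <- setdiff(need, names(j))
  if (length(miss))
    stop("missing field(s): ", paste(miss, collapse = ", "), " in ", path)
  injection_schedule(
    concentrations_M = j$concentrations_nM * 1e-9,
    association_s = j$association_s,
    inter_dissociation_s = j$inter_dissociation_s %||% 120,
    final_dissociation_s = j$final_dissociation_s %||% 1200,
    sample_rate = j$sample_rate %||% 10)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a machine + human report for a set of fit results
#'
#' Writes `report.json` (full numeric content plus provenance: seeds,
#' package version, configs) and `report.md` (a readable KD table) to
#' `out_dir`. Byte-identical for identical inputs.
#'
#' @param results Named list of `binding_fit` objects.
#' @param out_dir Output directory (created if missing).
#' @param seeds Optional named list/vector of seeds used upstream.
#' @return Paths of the two files, invisibly.
#' @export
run_report <- function(results, out_dir, seeds = NULL) {
  stopifnot(length(results) >= 1, !is.null(names(results)),
            all(nzchar(names(results))))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ver <- as.character(utils::packageVersion("sumdkin"))
  entry <- function(f) {
    e <- list(model = f$model, converged = isTRUE(f$converged))
    if (!is.null(f$params)) {
      pv <- if (inherits(f$params, c("one_to_one_params",
                                     "two_state_params")))
        unlist(unclass(f$params)) else f$params
      e$params <- as.list(pv)
      e$kd_nM <- f$derived_kd_nM
      e$residual_sse <- f$residual_sse
      e$n_points <- f$n_points
    }
    e
  }
  payload <- list(tool = "sumdkin", version = ver,
                  seeds = seeds, results = lapply(results, entry))
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  md <- c("# Binding fit report", "",
          paste0("tool: sumdkin ", ver), "",
          "| name | model | converged | KD (nM) | SSE (RU^2) | n |",
          "|---|---|---|---|---|---|")
  for (nm in names(results)) {
    f <- results[[nm]]
    md <- c(md, sprintf("| %s | %s | %s | %s | %s | %s |", nm, f$model,
                        isTRUE(f$converged),
                        if (is.null(f$derived_kd_nM) ||
                            is.na(f$derived_kd_nM)) "-" else
                          signif(f$derived_kd_nM, 3),
                        if (is.null(f$residual_sse)) "-" else
                          signif(f$residual_sse, 4),
                        if (is.null(f$n_points)) "-" else f$n_points))
  }
  md_path <- file.path(out_dir, "report.md")
  writeLines(md, md_path)
  invisible(c(json = json_path, md = md_path))
}
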