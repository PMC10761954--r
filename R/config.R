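UNIT_CONC <- c(mM = 1, uM = 1e-3, "µM" = 1e-3, M = 1e3)
UNIT_TIME <- c(h = 1, hr = 1, hour = 1, min = 1 / 60, s = 1 / 3600)

#' Read and validate a reaction-system configuration file
#'
#' Loads a YAML or JSON configuration with blocks `compounds` (each with
#' `id` and the species ids `amine_S`, `amine_R`, `ketone`), `reactions`
#' (`label`, `donor`, `ketone`, `k_OD`, `k_RA`), `enzyme` (`total`,
#' `initial_E_PLP_fraction`) and `initial_concentrations`, plus an
#' optional `units` block (`concentration`: mM/uM/M, `time`: h/min/s).
#' Declared units are converted to the internal mM/hour system on load;
#' rate constants scale as (concentration x time)^-1. All schema
#' violations are collected and reported together. The shipped schema
#' document is at `system.file("schema", "system-config.schema.json",
#' package = "racekin")`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [reaction_system()] (internal mM/h units), with
#'   attributes `units` (the declared units) and `config_md5` (hash of
#'   the file, for reproducibility logs).
#' @export
read_system_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)

  errs <- character()
  units <- cfg$units
  conc_u <- if (is.null(units$concentration)) "mM" else units$concentration
  time_u <- if (is.null(units$time)) "h" else units$time
  if (!conc_u %in% names(UNIT_CONC))
    errs <- c(errs, sprintf("unknown concentration unit '%s'", conc_u))
  if (!time_u %in% names(UNIT_TIME))
    errs <- c(errs, sprintf("unknown time unit '%s'", time_u))
  if (is.null(cfg$compounds)) errs <- c(errs, "missing block: compounds")
  if (is.null(cfg$reactions)) errs <- c(errs, "missing block: reactions")
  if (is.null(cfg$enzyme) || is.null(cfg$enzyme$total))
    errs <- c(errs, "missing block: enzyme (with field 'total')")
  if (length(errs))
    stop(paste0("invalid configuration:\n  - ",
                paste(errs, collapse = "\n  - ")), call. = FALSE)
  cf <- UNIT_CONC[[conc_u]]           # mM per declared unit
  tf <- UNIT_TIME[[time_u]]           # h per declared unit
  kf <- 1 / (cf * tf)                 # (mM^-1 h^-1) per declared k unit

  sp <- NULL
  for (cp in cfg$compounds) {
    if (is.null(cp$id)) { errs <- c(errs, "compound without id"); next }
    if (!is.null(cp$amine_S))
      sp <- rbind(sp, species(cp$amine_S, "amine_S", cp$id))
    if (!is.null(cp$amine_R))
      sp <- rbind(sp, species(cp$amine_R, "amine_R", cp$id))
    if (!is.null(cp$ketone))
      sp <- rbind(sp, species(cp$ketone, "ketone", cp$id))
    if (is.null(cp$amine_S) && is.null(cp$amine_R))
      errs <- c(errs, sprintf("compound %s declares no amine species", cp$id))
  }
  rx <- list()
  for (r in cfg$reactions) {
    miss <- setdiff(c("label", "donor", "ketone", "k_OD", "k_RA"), names(r))
    if (length(miss)) {
      errs <- c(errs, sprintf("reaction %s: missing field(s) %s",
                              if (is.null(r$label)) "<unlabeled>" else r$label,
                              paste(miss, collapse = ", ")))
      next
    }
    rx <- c(rx, list(elemental_reaction(r$label, r$donor, r$ketone,
                                        r$k_OD * kf, r$k_RA * kf)))
  }
  if (length(errs))
    stop(paste0("invalid configuration:\n  - ",
                paste(errs, collapse = "\n  - ")), call. = FALSE)
  init <- unlist(cfg$initial_concentrations)
  if (is.null(init)) init <- numeric()
  fr <- cfg$enzyme$initial_E_PLP_fraction
  sys <- reaction_system(
    species = sp, reactions = rx,
    enzyme_total = cfg$enzyme$total * cf,
    initial_concentrations = init * cf,
    initial_E_PLP_fraction = if (is.null(fr)) 1 else fr)
  attr(sys, "units") <- c(concentration = conc_u, time = time_u)
  attr(sys, "config_md5") <- unname(tools::md5sum(path))
  sys
}

#' Write a trajectory to CSV
#'
#' Columns: `time_h`, one per species id, `E_PLP`, `E_PMP` and
#' `ee_<compound>` for every chiral compound; full precision so a
#' re-read reproduces the values bit-identically. A second CSV of rate
#' traces (`time_h`, `label`, `v_OD`, `v_RA`, `v_net`) is written when
#' `rates_path` is given.
#'
#' @param traj A `trajectory`.
#' @param path Output CSV path.
#' @param rates_path Optional rate-trace CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, rates_path = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  df <- as.data.frame(traj)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(rates_path))
    utils::write.csv(format(traj$rates, digits = 17, trim = TRUE),
                     rates_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path CSV path.
#' @return A `data.frame` with numeric columns.
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Write a NAT geometry report as JSON
#'
#' The JSON layout follows the schema shipped at
#' `system.file("schema", "geometry-report.schema.json",
#' package = "racekin")`.
#'
#' @param report A `nat_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_geometry_report <- function(report, path) {
  stopifnot(inherits(report, "nat_report"))
  obj <- list(d_NAT = report$d_NAT, theta_BD = report$theta_BD,
              theta_DH = report$theta_DH,
              d_Halpha_Neps = report$d_Halpha_Neps,
              halpha_same_face = report$halpha_same_face,
              verdict = report$verdict,
              reasons = as.list(report$reasons))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read replicate initial-rate assays from CSV + sidecar
#'
#' The CSV must carry columns `replicate_id`, `time_h` (or `time` in the
#' sidecar's declared unit) and `product_mM` (or `product`); the sidecar
#' YAML declares `enzyme`, `substrate0` and optionally `units` and
#' `cosubstrate`. Units are converted to mM/h on load.
#'
#' @param csv_path Path to the measurements CSV.
#' @param sidecar_path Path to the sidecar YAML.
#' @return A list of [rate_assay()] objects, one per replicate.
#' @export
read_assay_csv <- function(csv_path, sidecar_path) {
  df <- utils::read.csv(csv_path)
  meta <- yaml::read_yaml(sidecar_path)
  if (is.null(meta$enzyme) || is.null(meta$substrate0))
    stop("sidecar must declare enzyme and substrate0", call. = FALSE)
  conc_u <- if (is.null(meta$units$concentration)) "mM" else
    meta$units$concentration
  time_u <- if (is.null(meta$units$time)) "h" else meta$units$time
  if (!conc_u %in% names(UNIT_CONC) || !time_u %in% names(UNIT_TIME))
    stop(sprintf("unknown units in sidecar: %s / %s", conc_u, time_u),
         call. = FALSE)
  cf <- UNIT_CONC[[conc_u]]; tf <- UNIT_TIME[[time_u]]
  tcol <- if ("time_h" %in% names(df)) "time_h" else "time"
  pcol <- if ("product_mM" %in% names(df)) "product_mM" else "product"
  if (!all(c("replicate_id", tcol, pcol) %in% names(df)))
    stop("assay CSV needs columns replicate_id, time(_h), product(_mM)",
         call. = FALSE)
  lapply(split(df, df$replicate_id), function(d) {
    d <- d[order(d[[tcol]]), ]
    rate_assay(d[[tcol]] * tf, d[[pcol]] * cf,
               enzyme = meta$enzyme * cf, substrate0 = meta$substrate0 * cf,
               cosubstrate = if (is.null(meta$cosubstrate)) NA_character_
               else meta$cosubstrate,
               replicate_id = as.character(d$replicate_id[1]))
  })
}
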