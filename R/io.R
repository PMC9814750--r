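#' Read a dielectric spectrum from CSV (+ optional JSON sidecar)
#'
#' Expects header columns `freq_GHz`, `eps_real`, `eps_imag`; sample
#' metadata (`peptide_conc_M`, `salt`, `salt_conc_M`, `temperature_K`) is
#' taken from a JSON sidecar `<file>.json` when present.
#'
#' @param path CSV file path.
#' @return a [dielectric_spectrum()].
#' @export
read_dielectric_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("freq_GHz", "eps_real", "eps_imag") %in% names(d)))
    stop("CSV must have columns freq_GHz, eps_real, eps_imag")
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  dielectric_spectrum(d$freq_GHz, d$eps_real, d$eps_imag, meta)
}

#' Write a dielectric spectrum to CSV (+ JSON sidecar)
#' @param spec a [dielectric_spectrum()].
#' @param path CSV file path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_dielectric_csv <- function(spec, path) {
  utils::write.csv(data.frame(freq_GHz = spec$freq, eps_real = spec$eps_real,
                              eps_imag = spec$eps_imag),
                   path, row.names = FALSE)
  jsonlite::write_json(spec$meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a peak-list CSV into a shift series
#'
#' Tidy format with columns `sample_id`, `c_titrant_M`, `proton_label`,
#' `delta_ppm`.
#'
#' @param path CSV file path.
#' @param ref_conc reference concentration (default: lowest in the file).
#' @param uncertainty reproducibility, ppm.
#' @param salt titrant identifier.
#' @return a [shift_series()].
#' @export
read_peaklist_csv <- function(path, ref_conc = NULL, uncertainty = 0.005,
                              salt = "titrant") {
  d <- utils::read.csv(path)
  need <- c("c_titrant_M", "proton_label", "delta_ppm")
  if (!all(need %in% names(d)))
    stop("CSV must have columns c_titrant_M, proton_label, delta_ppm")
  conc <- sort(unique(d$c_titrant_M))
  labs <- unique(d$proton_label)
  m <- matrix(NA_real_, length(conc), length(labs),
              dimnames = list(NULL, labs))
  for (i in seq_along(conc))
    for (j in labs) {
      v <- d$delta_ppm[d$c_titrant_M == conc[i] & d$proton_label == j]
      if (length(v) != 1) stop("exactly one shift per (concentration, proton) required")
      m[i, j] <- v
    }
  if (is.null(ref_conc)) ref_conc <- conc[1]
  shift_series(conc, m, ref_conc = ref_conc, uncertainty = uncertainty,
               salt = salt)
}

#' Write a shift series to a tidy peak-list CSV
#' @param series a [shift_series()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_peaklist_csv <- function(series, path) {
  rows <- expand.grid(i = seq_along(series$conc),
                      proton_label = colnames(series$shifts),
                      stringsAsFactors = FALSE)
  d <- data.frame(sample_id = sprintf("%s_%0.2fM", series$salt,
                                      series$conc[rows$i]),
                  c_titrant_M = series$conc[rows$i],
                  proton_label = rows$proton_label,
                  delta_ppm = series$shifts[cbind(rows$i,
                                                  match(rows$proton_label,
                                                        colnames(series$shifts)))])
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a 2D spectrum series as CSV matrices plus a metadata JSON
#'
#' One `signal_T2_<fs>.csv` matrix per waiting time, `pump.csv`/`probe.csv`
#' axis vectors and `meta.json` in `dir`.
#'
#' @param spectra list of [twodir_spectrum()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_2dir_dir <- function(spectra, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s1 <- spectra[[1]]
  utils::write.csv(data.frame(pump_cm = s1$pump),
                   file.path(dir, "pump.csv"), row.names = FALSE)
  utils::write.csv(data.frame(probe_cm = s1$probe),
                   file.path(dir, "probe.csv"), row.names = FALSE)
  for (s in spectra)
    utils::write.table(s$signal,
                       file.path(dir, sprintf("signal_T2_%d.csv",
                                              round(s$T2_fs))),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(T2_fs = vapply(spectra, function(s) s$T2_fs, numeric(1)),
         sign_convention = "bleach negative, ESA positive",
         band_centers = vapply(s1$meta$bands,
                               function(b) b$center, numeric(1))),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a 2D spectrum series written by [write_2dir_dir()]
#' @param dir directory containing the CSV matrices and `meta.json`.
#' @return list of [twodir_spectrum()].
#' @export
read_2dir_dir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  pump <- utils::read.csv(file.path(dir, "pump.csv"))$pump_cm
  probe <- utils::read.csv(file.path(dir, "probe.csv"))$probe_cm
  lapply(meta$T2_fs, function(Tw) {
    m <- as.matrix(utils::read.table(
      file.path(dir, sprintf("signal_T2_%d.csv", round(Tw))), sep = ","))
    dimnames(m) <- NULL
    twodir_spectrum(pump, probe, m, Tw,
                    meta = list(bands = lapply(meta$band_centers,
                                               function(cc) list(center = cc))))
  })
}
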