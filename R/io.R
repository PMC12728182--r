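# Delimited-text table formats and the YAML run configuration. Writers emit
# deterministic output; all tables are plain tab-separated text.

#' Write/read a CEST profile table
#'
#' One row per point: residue_id, B1_Hz, scheme (cw|dante), dante_window_Hz,
#' offset_Hz, intensity, sigma, is_reference. Reference rows carry the
#' unsaturated intensity that normalizes the profile.
#'
#' @param dataset a \linkS4class{CestDataset}
#' @param path output file
#' @export
writeProfileTable <- function(dataset, path) {
  rows <- lapply(dataset@profiles, function(p) {
    e <- p@experiment
    rbind(
      data.frame(residue_id = p@residueId, B1_Hz = e@B1, scheme = e@irradiation,
                 dante_window_Hz = ifelse(is.na(e@danteWindow), 0, e@danteWindow),
                 offset_Hz = NA_real_, intensity = 1, sigma = 0, is_reference = 1L),
      data.frame(residue_id = p@residueId, B1_Hz = e@B1, scheme = e@irradiation,
                 dante_window_Hz = ifelse(is.na(e@danteWindow), 0, e@danteWindow),
                 offset_Hz = p@offsets, intensity = p@intensities,
                 sigma = p@sigmas, is_reference = 0L))
  })
  tab <- do.call(rbind, rows)
  write.table(format(tab, digits = 10, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfileTable
#' @param composition a \linkS4class{MixtureComposition} for the returned
#'   dataset
#' @param Tsat saturation period (s)
#' @param larmor15N 15N Larmor frequency (MHz)
#' @param carrier carrier position (ppm)
#' @return \code{readProfileTable} returns a \linkS4class{CestDataset}
#' @export
readProfileTable <- function(path, composition, Tsat = 0.4, larmor15N = 96.3,
                             carrier = 118.5) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  key <- paste(tab$residue_id, tab$B1_Hz, tab$scheme)
  profiles <- lapply(unique(key), function(k) {
    sub <- tab[key == k, ]
    ref <- sub$intensity[sub$is_reference == 1]
    I0 <- if (length(ref)) mean(ref) else 1
    sub <- sub[sub$is_reference == 0, ]
    sub <- sub[order(sub$offset_Hz), ]
    expt <- CestExperiment(B1 = sub$B1_Hz[1], Tsat = Tsat,
                           irradiation = sub$scheme[1],
                           danteWindow = if (sub$dante_window_Hz[1] > 0)
                             sub$dante_window_Hz[1] else NA_real_,
                           larmor15N = larmor15N, carrier = carrier,
                           offsets = sub$offset_Hz)
    new("CestProfile", residueId = as.integer(sub$residue_id[1]),
        experiment = expt, offsets = sub$offset_Hz,
        intensities = sub$intensity / I0, sigmas = sub$sigma / I0,
        mask = rep(TRUE, nrow(sub)))
  })
  CestDataset(profiles, composition)
}

#' Write/read a relaxation decay table
#'
#' Columns: residue_id, delay_s, intensity, plane_sigma.
#' @param curves list of \linkS4class{DecayCurve}
#' @param path file path
#' @export
writeDecayTable <- function(curves, path) {
  tab <- do.call(rbind, lapply(curves, function(cv)
    data.frame(residue_id = cv@residueId, delay_s = cv@delays,
               intensity = cv@intensities, plane_sigma = cv@planeNoise)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDecayTable
#' @return \code{readDecayTable} returns a list of \linkS4class{DecayCurve}
#' @export
readDecayTable <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  lapply(split(tab, tab$residue_id), function(sub)
    DecayCurve(sub$residue_id[1], sub$delay_s, sub$intensity, sub$plane_sigma))
}

#' Write/read an ITC injection table
#'
#' Columns: temperature_K, injection_index, volume_uL, heat_uJ, segment_id,
#' cell_volume_uL, cell_conc_uM, syringe_conc_uM, replicate.
#' @param series list of \linkS4class{InjectionSeries}
#' @param path file path
#' @export
writeInjectionTable <- function(series, path) {
  rows <- lapply(seq_along(series), function(i) {
    s <- series[[i]]
    data.frame(temperature_K = s@temperature,
               injection_index = seq_along(s@volumes),
               volume_uL = s@volumes, heat_uJ = s@heats,
               segment_id = s@segments, cell_volume_uL = s@cellVolume,
               cell_conc_uM = s@cellConc, syringe_conc_uM = s@syringeConc,
               replicate = i)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeInjectionTable
#' @return \code{readInjectionTable} returns a list of
#'   \linkS4class{InjectionSeries}
#' @export
readInjectionTable <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  lapply(split(tab, tab$replicate), function(sub) {
    sub <- sub[order(sub$injection_index), ]
    InjectionSeries(sub$temperature_K[1], sub$cell_volume_uL[1],
                    sub$cell_conc_uM[1], sub$syringe_conc_uM[1],
                    sub$volume_uL, sub$heat_uJ, sub$segment_id)
  })
}

#' Read a YAML run configuration
#'
#' Expected sections: \code{experiment} (Tsat, larmor15N, carrier),
#' \code{constraint} (Kd_uM, P0_uM, R0_uM), \code{model} (model, crib_range,
#' excluded_residues, tie_r2bc), \code{bootstrap} (n, seed), \code{itc}
#' (cell_volume_uL, cell_conc_uM, syringe_conc_uM), \code{exchange}
#' (kon, koff, kAB, kBA, kBC, kCB, model), \code{paths} (profile_table,
#' decay_table, injection_table, out_dir).
#'
#' @param path YAML file
#' @return nested list
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

#' Serialize an exchange scheme to/from a config list
#'
#' @param scheme an \linkS4class{ExchangeScheme}
#' @return \code{schemeToConfig}: a named list matching the
#'   \code{exchange} config section
#' @export
schemeToConfig <- function(scheme) {
  g <- as.list(c(kon = scheme@kon, koff = scheme@koff))
  if (nStates(scheme) == 4) {
    g$kAB <- unname(scheme@kFwd["AB"]); g$kBA <- unname(scheme@kRev["BA"])
  }
  g$kBC <- unname(scheme@kFwd["BC"]); g$kCB <- unname(scheme@kRev["CB"])
  g$model <- if (nStates(scheme) == 4) "4site" else "3site"
  g
}

#' @rdname schemeToConfig
#' @param config a named list with keys kon, koff, kAB, kBA, kBC, kCB, model
#' @export
schemeFromConfig <- function(config) {
  if (identical(config$model, "3site"))
    ExchangeScheme("3site", kon = config$kon, koff = config$koff,
                   kBC = config$kBC, kCB = config$kCB)
  else
    ExchangeScheme("4site", kon = config$kon, koff = config$koff,
                   kAB = config$kAB, kBA = config$kBA,
                   kBC = config$kBC, kCB = config$kCB)
}
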