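# High-level coarse-grained 2DES driver and file formats.
#
# The expensive stage (doorway/window tables, one propagation pass per
# segment) is computed once and reused for every waiting time: a transfer
# map and the response assembly are all that changes with t2.

#' Doorway and window tables for every segment
#'
#' One long trajectory is generated per call; doorway averages and window
#' averages use starting points offset by half the spacing, so the two
#' ensemble averages run over distinct trajectory stretches (statistically
#' independent, consistent with waiting times long compared to the bath
#' memory).  Equilibrium density matrices are the HT identity/D or
#' finite-temperature trajectory-averaged Boltzmann operators.
#'
#' @param system a [system_model()]
#' @param nt1,nt3 coherence grid lengths
#' @param realizations starting points per ensemble average
#' @param seed master seed
#' @param dt time step (fs)
#' @param spacing frames between starting points (default `max(nt1, nt3)`)
#' @param basis_mode two-exciton mode, `"strict"` or `"paper"`
#' @param anharmonicity same-site pair shift (cm^-1), paper mode
#' @param rho_stride frame stride for the equilibrium-density average
#' @return list with `doorways`, `windows`, `rhos`, `traj` and settings
#' @export
cg_segment_tables <- function(system, nt1, nt3, realizations = 100L,
                              seed = 1L, dt = 2, spacing = NULL,
                              basis_mode = "strict", anharmonicity = 0,
                              rho_stride = 20L) {
  S <- length(system$seg$D)
  if (is.null(spacing)) spacing <- max(nt1, nt3)
  w_off <- spacing %/% 2L
  nf <- max(frames_needed(realizations, spacing, nt1),
            frames_needed(realizations, spacing, nt3, w_off))
  traj <- default_trajectory(system, nf, dt, seed)
  doorways <- vector("list", S)
  windows <- vector("list", S)
  rhos <- vector("list", S)
  for (j in seq_len(S)) {
    Dj <- length(segment_sites(system$seg, j))
    rho <- equilibrium_density(traj, system$J, system$seg, j,
                               system$temperature, frame_stride = rho_stride)
    basis <- if (Dj >= 2L)
      build_two_exciton_basis(Dj, basis_mode, anharmonicity) else NULL
    doorways[[j]] <- doorway(system, j, nt1, realizations, traj = traj,
                             spacing = spacing, offset = 0L)
    windows[[j]] <- list(
      GB = window_gb(system, j, nt3, realizations, traj = traj,
                     spacing = spacing, offset = w_off),
      SE = window_se(system, j, rho, nt3, realizations, traj = traj,
                     spacing = spacing, offset = w_off),
      EA = window_ea(system, j, rho, nt3, basis = basis,
                     realizations = realizations, traj = traj,
                     spacing = spacing, offset = w_off))
    rhos[[j]] <- rho
  }
  list(doorways = doorways, windows = windows, rhos = rhos, traj = traj,
       nt1 = nt1, nt3 = nt3, realizations = realizations, seed = seed,
       spacing = spacing, dt = dt)
}

#' Coarse-grained 2DES spectra over a set of waiting times
#'
#' Computes (or reuses) the segment doorway/window tables, then for every
#' waiting time builds the transfer map, assembles both pathways and
#' Fourier transforms to the absorptive spectrum.
#'
#' @param system a [system_model()]
#' @param K segment rate matrix (ps^-1), see [validate_rate_matrix()]
#' @param t2_values waiting times (ps)
#' @param scheme polarization scheme for the orientational weights
#' @param gb_kernel `"eq17"` or `"identity"`, see [assemble_response()]
#' @param ref_freq carrier frequency (cm^-1); default dipole-weighted mean
#'   site energy
#' @param zero_pad FFT padding factor
#' @param tables optional precomputed [cg_segment_tables()] result (cache)
#' @inheritParams cg_segment_tables
#' @return list with `spectra` (one `spectrum2d` per t2), `tables`,
#'   `responses`
#' @export
cg_2des <- function(system, K, t2_values = 0, nt1 = 128L, nt3 = 128L,
                    realizations = 100L, seed = 1L, dt = 2,
                    scheme = "parallel", gb_kernel = "eq17",
                    ref_freq = NULL, zero_pad = 4L, tables = NULL, ...) {
  K <- validate_rate_matrix(K)
  if (is.null(tables))
    tables <- cg_segment_tables(system, nt1, nt3, realizations, seed, dt, ...)
  if (is.null(ref_freq)) {
    w <- rowSums(system$dipoles^2)
    ref_freq <- sum(system$means * w) / sum(w)
  }
  A <- orientational_weights(scheme)
  spectra <- list(); responses <- list()
  for (ti in seq_along(t2_values)) {
    Tm <- transfer_map(K, t2_values[ti])
    nr <- assemble_response(tables$doorways, tables$windows, Tm, A,
                            "nonrephasing", gb_kernel)
    rp <- assemble_response(tables$doorways, tables$windows, Tm, A,
                            "rephasing", gb_kernel)
    spectra[[ti]] <- spectrum_2d(nr, rp, ref_freq, zero_pad)
    responses[[ti]] <- list(nonrephasing = nr, rephasing = rp)
  }
  list(spectra = spectra, responses = responses, tables = tables,
       t2_values = t2_values, ref_freq = ref_freq, scheme = scheme,
       gb_kernel = gb_kernel)
}

# model files ----------------------------------------------------------------

#' Write a system model to a structured text file
#'
#' Key/value header (format tag, units, temperature, site count) followed
#' by the per-site table (mean energy, sigma, correlation time, dipole
#' x/y/z, segment id) and the coupling-matrix block.
#'
#' @param system a [system_model()]
#' @param path output path
#' @export
write_model <- function(system, path) {
  N <- system$seg$N
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "format: cg2des-model v1",
    "units: energy cm-1, time fs, dipoles arbitrary",
    paste0("temperature: ", if (is.infinite(system$temperature)) "Inf"
           else format(system$temperature)),
    paste0("sites: ", N),
    "# mean sigma lambda_inv mu_x mu_y mu_z segment"), con)
  num <- function(x) formatC(x, digits = 12, format = "g")
  rows <- vapply(seq_len(N), function(i) paste(
    num(system$means[i]), num(system$bath$sigma[i]),
    num(system$bath$lambda_inv[i]), num(system$dipoles[i, 1L]),
    num(system$dipoles[i, 2L]), num(system$dipoles[i, 3L]),
    system$seg$assignment[i]), character(1))
  writeLines(rows, con)
  writeLines("couplings:", con)
  utils::write.table(format(system$J, digits = 12), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a system model from a structured text file
#'
#' @param path file written by [write_model()] (or hand-authored in the
#'   same format)
#' @return a [system_model()]
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_invalid("model file not found: ", path)
  lines <- readLines(path)
  fail <- function(ln, msg) stop_invalid(path, ":", ln, ": ", msg)
  get_field <- function(key) {
    hit <- grep(paste0("^", key, ":"), lines)
    if (length(hit) == 0L) fail(0L, paste0("missing header field `", key, "`"))
    list(value = trimws(sub(paste0("^", key, ":"), "", lines[hit[1L]])),
         line = hit[1L])
  }
  fmt <- get_field("format")
  if (!startsWith(fmt$value, "cg2des-model"))
    fail(fmt$line, "unrecognised format tag")
  temp <- get_field("temperature")
  temperature <- if (toupper(temp$value) %in% c("INF", "HT")) Inf else {
    tv <- suppressWarnings(as.numeric(temp$value))
    if (is.na(tv)) fail(temp$line, "temperature must be a number or Inf")
    tv
  }
  ns <- get_field("sites")
  N <- suppressWarnings(as.integer(ns$value))
  if (is.na(N) || N < 1L) fail(ns$line, "sites must be a positive integer")
  body <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  body <- body[body > max(fmt$line, temp$line, ns$line)]
  cpl <- grep("^couplings:", lines)
  if (length(cpl) == 0L) fail(length(lines), "missing `couplings:` block")
  site_lines <- body[body < cpl[1L]]
  if (length(site_lines) != N)
    fail(cpl[1L], paste0("expected ", N, " site rows, found ",
                         length(site_lines)))
  parse_row <- function(ln, nfield, what) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[ln]), "\\s+")[[1L]]))
    if (length(v) != nfield || any(is.na(v)))
      fail(ln, paste0("malformed ", what, " row (need ", nfield,
                      " numeric fields)"))
    v
  }
  site_tab <- t(vapply(site_lines, parse_row, numeric(7L), nfield = 7L,
                       what = "site"))
  seg_ids <- as.integer(site_tab[, 7L])
  if (any(seg_ids < 1L))
    fail(site_lines[which(seg_ids < 1L)[1L]],
         paste0("site ", which(seg_ids < 1L)[1L],
                " has no valid segment assignment"))
  coup_lines <- body[body > cpl[1L]]
  if (length(coup_lines) != N)
    fail(cpl[1L], paste0("expected ", N, " coupling rows, found ",
                         length(coup_lines)))
  J <- t(vapply(coup_lines, parse_row, numeric(N), nfield = N,
                what = "coupling"))
  system_model(means = site_tab[, 1L],
               bath = bath_params(site_tab[, 2L], site_tab[, 3L]),
               J = J, dipoles = site_tab[, 4:6],
               seg = segmentation(seg_ids), temperature = temperature)
}

#' Write a 2D spectrum as delimited text
#'
#' Long format: `omega1 omega3 absorptive`, with axes in cm^-1 and header
#' comments recording the waiting time, normalization and config hash.
#'
#' @param spec a `spectrum2d`
#' @param path output path
#' @param config_hash optional provenance string embedded in the header
#' @param normalized divide by the spectrum's own absolute maximum
#' @export
write_spectrum <- function(spec, path, config_hash = NULL, normalized = TRUE) {
  con <- file(path, "w"); on.exit(close(con))
  v <- spec$absorptive
  if (normalized && spec$peak > 0) v <- v / spec$peak
  writeLines(c("# cg2des absorptive 2D spectrum",
               paste0("# t2_ps: ", format(spec$t2)),
               paste0("# normalized: ", normalized,
                      "  peak: ", format(spec$peak)),
               if (!is.null(config_hash)) paste0("# config_hash: ", config_hash),
               "omega1 omega3 value"), con)
  grid <- cbind(rep(spec$omega1, times = length(spec$omega3)),
                rep(spec$omega3, each = length(spec$omega1)),
                as.vector(v))
  utils::write.table(format(grid, digits = 8), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

config_hash <- function(config) {
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

default_run_config <- function() {
  list(fixture = "dimer_double", regime = "HT", temperature = "Inf",
       nt1 = 64L, nt3 = 64L, dt = 2, t2_ps = c(0, 5, 20),
       realizations = 40L, seed = 1L, scheme = "parallel",
       gb_kernel = "eq17", zero_pad = 4L)
}

#' Read a run configuration from a JSON file
#' @param path JSON file with any subset of the configuration fields;
#'   unset fields take the documented defaults
#' @return config list
#' @export
read_run_config <- function(path) {
  cfg <- utils::modifyList(default_run_config(),
                           jsonlite::read_json(path, simplifyVector = TRUE))
  cfg
}

#' Run the coarse-grained 2DES pipeline
#'
#' Loads or builds the system model and rate matrix, computes (or reuses
#' cached) doorway/window tables, assembles spectra for every waiting
#' time, and writes all artifacts plus a structured JSON log into
#' `outdir`.  Rerunning with an extended `t2_ps` list reuses the cached
#' tables: only the new transfer maps and assemblies are computed.
#'
#' @param config list (see `read_run_config`); recognised fields include
#'   `model` (path) or `fixture` (`"dimer_single"`, `"dimer_double"`,
#'   `"two_ring"`), `rates` (path) or `regime` (`"HT"`/`"RT"`),
#'   `temperature`, grids `nt1`/`nt3`/`dt`, `t2_ps`, `realizations`,
#'   `seed`, `scheme`, `gb_kernel`, `zero_pad`
#' @param outdir output directory (created if needed)
#' @return invisible list with the computed spectra and file paths
#' @export
run_pipeline <- function(config = list(), outdir = "cg2des_out") {
  cfg <- utils::modifyList(default_run_config(), config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg[setdiff(names(cfg), "t2_ps")])
  log <- list(config = cfg, config_hash = hash,
              package_version = as.character(utils::packageVersion("cg2des")),
              stages = list())
  note <- function(stage, msg) {
    message("[cg2des:", stage, "] ", msg)
    log$stages[[stage]] <<- c(log$stages[[stage]], msg)
  }
  temperature <- if (identical(cfg$temperature, "Inf")) Inf
                 else as.numeric(cfg$temperature)
  system <- if (!is.null(cfg$model)) {
    note("model", paste("loaded", cfg$model))
    load_model(cfg$model)
  } else switch(cfg$fixture,
    dimer_single = make_dimer_fixture("single_segment", temperature),
    dimer_double = make_dimer_fixture("double_segment", temperature),
    two_ring = make_two_ring_fixture(temperature = temperature),
    stop_invalid("unknown fixture: ", cfg$fixture))
  if (is.null(cfg$model)) note("model", paste("fixture", cfg$fixture))
  S <- length(system$seg$D)
  K <- if (!is.null(cfg$rates)) {
    note("rates", paste("loaded", cfg$rates))
    read_rate_matrix(cfg$rates)
  } else if (S == 2L) {
    note("rates", paste("dimer fixture rates,", cfg$regime))
    build_dimer_rate_fixture(cfg$regime)
  } else if (S == 10L) {
    note("rates", paste("LH2 fixture rates,", cfg$regime))
    build_lh2_rate_fixture(cfg$regime)
  } else if (S == 1L) {
    validate_rate_matrix(matrix(0, 1L, 1L))
  } else stop_invalid("no rate matrix available for ", S, " segments; ",
                      "supply `rates`")
  if (nrow(K) != S)
    stop_invalid("rate matrix has ", nrow(K), " segments, system has ", S)
  cache_file <- file.path(outdir, paste0("tables_", hash, ".rds"))
  if (file.exists(cache_file)) {
    tables <- readRDS(cache_file)
    note("tables", "reused cached doorway/window tables")
  } else {
    tables <- cg_segment_tables(system, cfg$nt1, cfg$nt3, cfg$realizations,
                                cfg$seed, cfg$dt)
    saveRDS(tables, cache_file)
    note("tables", "computed doorway/window tables")
  }
  res <- cg_2des(system, K, cfg$t2_ps, scheme = cfg$scheme,
                 gb_kernel = cfg$gb_kernel, zero_pad = cfg$zero_pad,
                 tables = tables)
  paths <- character(0)
  for (ti in seq_along(cfg$t2_ps)) {
    p <- file.path(outdir, sprintf("spectrum_t2_%gps.txt", cfg$t2_ps[ti]))
    write_spectrum(res$spectra[[ti]], p, config_hash = hash)
    paths <- c(paths, p)
  }
  note("spectra", paste("wrote", length(paths), "spectra"))
  log$outputs <- paths
  logp <- file.path(outdir, "run_log.json")
  jsonlite::write_json(log, logp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(res, list(paths = paths, log = logp, config_hash = hash)))
}
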