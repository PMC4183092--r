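# Text file formats. All products carry a header of "# key value" lines
# including the config hash of the run that produced them, so an archive is
# self-describing and a rerun from the archived seeds reproduces it.

write_header <- function(con, meta) {
  for (nm in names(meta)) writeLines(sprintf("# %s %s", nm, meta[[nm]]), con)
}

read_header <- function(path) {
  lines <- readLines(path, n = 50)
  hdr <- lines[startsWith(lines, "# ")]
  kv <- strsplit(sub("^# ", "", hdr), " ", fixed = TRUE)
  out <- lapply(kv, function(z) paste(z[-1], collapse = " "))
  names(out) <- vapply(kv, `[[`, character(1), 1)
  out
}

#' Write / read a spike raster as columnar text
#'
#' Format: `# key value` header lines (config hash, bin width, trial count,
#' duration, transient, neuron count) followed by whitespace-separated
#' columns `trial neuron time`.
#'
#' @param raster A `"spike_raster"`.
#' @param path Output file.
#' @return `write_raster` returns `path` invisibly; `read_raster` returns a
#'   `"spike_raster"` (without any phase store).
#' @export
write_raster <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, list(
    config_hash = raster$config_hash, dt_bin = raster$dt_bin,
    n_trials = raster$n_trials, n_neurons = raster$n_neurons,
    duration = raster$duration, transient = raster$transient,
    input_seed = raster$input_seed,
    populations = paste(raster$populations, collapse = "")
  ))
  writeLines("trial neuron time", con)
  write.table(raster$spikes, con, row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  hdr <- read_header(path)
  sp <- read.table(path, header = TRUE, comment.char = "#")
  structure(
    list(spikes = sp, n_neurons = as.integer(hdr$n_neurons),
         n_trials = as.integer(hdr$n_trials),
         duration = as.numeric(hdr$duration),
         dt_bin = as.numeric(hdr$dt_bin),
         transient = as.numeric(hdr$transient),
         populations = strsplit(hdr$populations, "")[[1]],
         config_hash = hdr$config_hash,
         input_seed = as.integer(hdr$input_seed), phases = NULL),
    class = "spike_raster"
  )
}

#' Write / read a coupling matrix as coordinate-list text
#'
#' @param cm A `"coupling_matrix"`.
#' @param path Output file.
#' @export
write_coupling <- function(cm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, list(N = cm$N, kappa = cm$kappa, seed = cm$seed,
                         populations = paste(cm$populations, collapse = "")))
  writeLines("i j a", con)
  trip <- methods::as(cm$A, "TsparseMatrix")
  df <- data.frame(i = trip@i + 1L, j = trip@j + 1L, a = trip@x)
  write.table(df, con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_coupling
#' @export
read_coupling <- function(path) {
  hdr <- read_header(path)
  df <- read.table(path, header = TRUE, comment.char = "#")
  N <- as.integer(hdr$N)
  A <- Matrix::sparseMatrix(i = df$i, j = df$j, x = df$a, dims = c(N, N))
  structure(
    list(A = methods::as(A, "CsparseMatrix"),
         populations = strsplit(hdr$populations, "")[[1]],
         N = N, kappa = as.numeric(hdr$kappa), seed = as.integer(hdr$seed)),
    class = "coupling_matrix"
  )
}

#' Write / read a Lyapunov spectrum as tabular text
#'
#' @param spectrum A `"lyapunov_spectrum"`.
#' @param path Output file.
#' @export
write_spectrum <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, list(N = spectrum$N, m = spectrum$m,
                         t_accum = spectrum$t_accum,
                         config_hash = spectrum$config_hash,
                         input_seed = spectrum$input_seed))
  writeLines("rank lambda_nats_per_tu", con)
  write.table(
    data.frame(rank = seq_along(spectrum$exponents),
               lambda = spectrum$exponents),
    con, row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  hdr <- read_header(path)
  df <- read.table(path, header = TRUE, comment.char = "#")
  structure(
    list(exponents = df[[2]], m = as.integer(hdr$m), N = as.integer(hdr$N),
         trace = NULL, t_accum = as.numeric(hdr$t_accum), t_ortho = NA,
         config_hash = hdr$config_hash,
         input_seed = as.integer(hdr$input_seed)),
    class = "lyapunov_spectrum"
  )
}

#' Write an entropy curve as tabular text
#'
#' @param curve Data frame from [entropy_curve()].
#' @param path Output file.
#' @param meta Optional named list for the header.
#' @export
write_entropy_table <- function(curve, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, meta)
  writeLines("L H_bits_per_tu windows trials", con)
  write.table(curve, con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flat key-value experiment configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Unknown keys are
#' errors, guarding against silent typos in parameter sweeps.
#'
#' @param path Configuration file.
#' @return A [network_config()] plus run keys (`trials`, `duration`).
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad)) stop("malformed config line(s): ", lines[bad][1], call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, character(1), 1))
  vals <- trimws(vapply(kv, `[[`, character(1), 2))
  allowed <- c("N", "kappa", "frac_inhib", "eta", "eps", "b", "d", "dt_int",
               "dt_bin", "model_variant", "transient", "burn", "master_seed",
               "trials", "duration")
  unknown <- setdiff(keys, allowed)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  conf <- as.list(vals)
  names(conf) <- keys
  num <- setdiff(allowed, "model_variant")
  for (k in intersect(names(conf), num)) conf[[k]] <- as.numeric(conf[[k]])
  cfg_keys <- setdiff(allowed, c("trials", "duration"))
  cfg <- do.call(network_config, conf[intersect(names(conf), cfg_keys)])
  list(cfg = cfg,
       trials = if (!is.null(conf$trials)) conf$trials else 10,
       duration = if (!is.null(conf$duration)) conf$duration else 100)
}

#' Run a simulation experiment and write an archive
#'
#' Orchestrates coupling construction, initial-condition sampling,
#' simulation, binarization, and the basic analyses, then writes a
#' self-describing archive directory of text products (config snapshot,
#' coupling matrix, spike raster, rate summary). Re-running with the
#' archived seeds reproduces the raster bit-identically.
#'
#' @param config A file path accepted by [read_config()], or a list with
#'   elements `cfg` (a [network_config()]), `trials`, `duration`.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param record_cells Optional neuron subset to record.
#' @return An `"experiment_archive"` list: config, coupling, raster,
#'   excitatory/inhibitory rates, and file paths.
#' @export
run_experiment <- function(config, out_dir = NULL, record_cells = NULL) {
  ex <- if (is.character(config)) read_config(config) else config
  cfg <- ex$cfg
  validate_config(cfg)
  A <- build_coupling_matrix(cfg)
  input <- generate_input(cfg, 0, ex$duration)
  ics <- sample_initial_ensemble(cfg, A, M = ex$trials)
  raster <- run_trials(cfg, A, input, ics, T = ex$duration,
                       record_cells = record_cells)
  rates <- c(exc = mean_firing_rate(raster, "exc"),
             inh = mean_firing_rate(raster, "inh"))
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      config = file.path(out_dir, "config.txt"),
      coupling = file.path(out_dir, "coupling.txt"),
      raster = file.path(out_dir, "raster.txt"),
      summary = file.path(out_dir, "summary.txt")
    )
    writeLines(c(
      sprintf("# config_hash %s", config_hash(cfg)),
      sprintf("N = %d", cfg$N), sprintf("kappa = %g", cfg$kappa),
      sprintf("frac_inhib = %g", cfg$frac_inhib),
      sprintf("eta = %g", cfg$eta), sprintf("eps = %g", cfg$eps),
      sprintf("b = %g", cfg$b), sprintf("d = %g", cfg$d),
      sprintf("dt_int = %g", cfg$dt_int), sprintf("dt_bin = %g", cfg$dt_bin),
      sprintf("model_variant = %s", cfg$model_variant),
      sprintf("transient = %g", cfg$transient),
      sprintf("burn = %g", cfg$burn),
      sprintf("master_seed = %d", cfg$master_seed),
      sprintf("trials = %d", as.integer(ex$trials)),
      sprintf("duration = %g", ex$duration)
    ), paths$config)
    write_coupling(A, paths$coupling)
    write_raster(raster, paths$raster)
    writeLines(c(
      sprintf("# config_hash %s", config_hash(cfg)),
      sprintf("exc_rate_spikes_per_tu %.6f", rates["exc"]),
      sprintf("inh_rate_spikes_per_tu %.6f", rates["inh"]),
      sprintf("n_spikes %d", nrow(raster$spikes))
    ), paths$summary)
  }
  structure(
    list(cfg = cfg, coupling = A, raster = raster, rates = rates,
         paths = paths),
    class = "experiment_archive"
  )
}
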