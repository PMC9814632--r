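#' Load a simulation configuration from YAML
#'
#' Reads a YAML file with the [simulation_config()] fields (`a`, `b`,
#' `sigma`, `c`, `dx`, `nx`, `ny`, `dt`, `noise_sd`, `seed`,
#' `snapshot_interval`) and a `stages:` list of `{duration, A, T}` entries.
#' Missing fields take the package defaults (reference numerics); unknown
#' keys are rejected by name.
#'
#' @param path Path to the YAML file.
#' @return A validated `simulation_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  raw <- yaml::read_yaml(path)
  allowed <- c("a", "b", "sigma", "c", "dx", "nx", "ny", "dt", "noise_sd",
               "seed", "snapshot_interval", "stages")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0)
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  if (is.null(raw$a)) stop("configuration must give the feed parameter 'a'")
  if (is.null(raw$stages) || length(raw$stages) == 0)
    stop("configuration must give a nonempty 'stages' list")
  stages <- lapply(raw$stages, function(st) {
    bad <- setdiff(names(st), c("duration", "A", "T"))
    if (length(bad) > 0)
      stop(sprintf("unknown stage key(s): %s", paste(bad, collapse = ", ")))
    if (is.null(st$duration)) stop("every stage needs a 'duration'")
    protocol_stage(duration = st$duration,
                   A = st$A %||% 0, T = st$T %||% 1)
  })
  params <- le_params(a = raw$a, b = raw$b %||% 1.9,
                      sigma = raw$sigma %||% 8, c = raw$c %||% 1.5)
  dx <- raw$dx %||% 0.125
  simulation_config(params, stages, dx = dx,
                    nx = raw$nx %||% round(50 / dx),
                    ny = raw$ny %||% raw$nx %||% round(50 / dx),
                    dt = raw$dt %||% 3.124e-4,
                    noise_sd = raw$noise_sd %||% 0.01,
                    seed = raw$seed %||% 1,
                    snapshot_interval = raw$snapshot_interval %||% 5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a simulation configuration to YAML
#'
#' Inverse of [load_config()]: writes all fields explicitly so the round
#' trip reproduces the configuration exactly.
#'
#' @param config A `simulation_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  p <- config$params
  out <- list(a = p$a, b = p$b, sigma = p$sigma, c = p$c,
              dx = config$dx, nx = config$nx, ny = config$ny,
              dt = config$dt, noise_sd = config$noise_sd,
              seed = config$seed,
              snapshot_interval = config$snapshot_interval,
              stages = lapply(config$stages, function(st)
                list(duration = st$duration, A = st$forcing$A,
                     T = st$forcing$T)))
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Persist snapshots
#'
#' Writes a snapshot list to disk.  The `rds` format round-trips field
#' arrays bit-exactly; `csv` writes one full-precision (17 significant
#' digits) file per field per frame into a directory, also bit-exact on
#' reread for doubles.
#'
#' @param snapshots List of [field_state()] objects.
#' @param path File path (`rds`) or directory (`csv`).
#' @param format `"rds"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
save_snapshots <- function(snapshots, path, format = c("rds", "csv")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(snapshots, path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    times <- vapply(snapshots, function(s) s$t, numeric(1))
    utils::write.csv(data.frame(frame = seq_along(times),
                                t = sprintf("%.17g", times)),
                     file.path(path, "times.csv"), row.names = FALSE,
                     quote = FALSE)
    for (i in seq_along(snapshots)) {
      write_field_csv(snapshots[[i]]$u,
                      file.path(path, sprintf("u_%04d.csv", i)))
      write_field_csv(snapshots[[i]]$v,
                      file.path(path, sprintf("v_%04d.csv", i)))
    }
  }
  invisible(path)
}

#' @rdname save_snapshots
#' @export
load_snapshots <- function(path, format = c("rds", "csv")) {
  format <- match.arg(format)
  if (format == "rds") return(readRDS(path))
  times <- utils::read.csv(file.path(path, "times.csv"),
                           colClasses = c("integer", "numeric"))
  lapply(seq_len(nrow(times)), function(i)
    field_state(read_field_csv(file.path(path, sprintf("u_%04d.csv", i))),
                read_field_csv(file.path(path, sprintf("v_%04d.csv", i))),
                t = times$t[i]))
}

write_field_csv <- function(mat, path) {
  txt <- apply(mat, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(txt, path)
}

read_field_csv <- function(path) {
  rows <- strsplit(readLines(path), ",", fixed = TRUE)
  do.call(rbind, lapply(rows, as.numeric))
}

#' Render a field to a grayscale PNG
#'
#' Writes the activator field as a grayscale image with fixed contrast
#' limits, for visual comparison across frames of a run.
#'
#' @param field Numeric matrix.
#' @param path Output PNG path.
#' @param zlim Contrast limits; defaults to the field range.
#' @return `path`, invisibly.
#' @export
render_field_png <- function(field, path, zlim = range(field)) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG rendering")
  z <- (field - zlim[1]) / max(zlim[2] - zlim[1], .Machine$double.eps)
  z[z < 0] <- 0
  z[z > 1] <- 1
  png::writePNG(t(z)[ncol(z):1, , drop = FALSE], path)
  invisible(path)
}

#' Synthetic pattern fixtures
#'
#' Generates snapshot sequences with known ground-truth labels for testing
#' the pattern analyzer: `spots-hex` is the sum of three cosine modes at
#' 120 degrees whose wavevectors sum to zero (hexagonal planform, skewed
#' about the mean), `stripes` a single cosine, `homogeneous` a constant
#' field, and `homogeneous-oscillatory` a spatially uniform sinusoid in
#' time.  Wavevectors are snapped to the periodic domain's reciprocal
#' lattice, so the realized wavenumber is the representable one closest to
#' `k`.
#'
#' @param kind One of `"spots-hex"`, `"stripes"`, `"homogeneous"`,
#'   `"homogeneous-oscillatory"`.
#' @param k Target wavenumber (must satisfy `k < pi / dx`).
#' @param nx,ny Grid size.
#' @param dx Grid spacing.
#' @param amplitude Pattern amplitude about the mean level.
#' @param mean_level Field mean.
#' @param noise_sd Optional additive Gaussian noise.
#' @param n_snapshots Number of frames.
#' @param period Oscillation period of the oscillatory fixture (frames span
#'   exactly one period).
#' @param seed RNG seed for the noise.
#' @return List of [field_state()] objects.
#' @examples
#' fx <- make_fixture("spots-hex", k = 1.2, nx = 128, ny = 128, dx = 0.25)
#' classify_pattern(fx, 0.25)$label
#' @export
make_fixture <- function(kind = c("spots-hex", "stripes", "homogeneous",
                                  "homogeneous-oscillatory"),
                         k = 1.2, nx = 128, ny = 128, dx = 0.25,
                         amplitude = 1, mean_level = 5, noise_sd = 0,
                         n_snapshots = 8, period = 1, seed = 1) {
  kind <- match.arg(kind)
  if (k >= pi / dx && kind %in% c("spots-hex", "stripes"))
    stop(sprintf("k = %g is not resolvable on a grid with dx = %g", k, dx))
  Lx <- nx * dx
  Ly <- ny * dx
  x <- (seq_len(nx) - 1) * dx
  y <- (seq_len(ny) - 1) * dx
  set.seed(seed)
  lattice_mode <- function(kvec) {
    m1 <- round(kvec[1] * Lx / (2 * pi))
    m2 <- round(kvec[2] * Ly / (2 * pi))
    c(2 * pi * m1 / Lx, 2 * pi * m2 / Ly)
  }
  base <- switch(kind,
    "stripes" = {
      kv <- lattice_mode(c(k, 0))
      outer(x, y, function(xx, yy) cos(kv[1] * xx + kv[2] * yy))
    },
    "spots-hex" = {
      k1 <- lattice_mode(c(k, 0))
      k2 <- lattice_mode(k * c(cos(2 * pi / 3), sin(2 * pi / 3)))
      k3 <- -(k1 + k2)  # closure keeps the three-mode resonance exact
      Reduce(`+`, lapply(list(k1, k2, k3), function(kv)
        outer(x, y, function(xx, yy) cos(kv[1] * xx + kv[2] * yy)))) / 1.5
    },
    matrix(0, nx, ny))
  noise <- if (noise_sd > 0)
    matrix(stats::rnorm(nx * ny, 0, noise_sd), nx, ny)
  else 0
  lapply(seq_len(n_snapshots), function(i) {
    tt <- (i - 1) * period / n_snapshots
    osc <- if (kind == "homogeneous-oscillatory")
      amplitude * sin(2 * pi * tt / period)
    else 0
    u <- mean_level + amplitude * base + osc + noise
    field_state(u, u, t = tt)
  })
}

#' Run manifest
#'
#' Summary record of a protocol run for reproducibility: a configuration
#' hash that is stable under field reordering, the seed, package version,
#' per-stage classification summaries and any declared output files.
#'
#' @param result A [run_protocol()] result.
#' @param files Character vector of output file paths to record (must
#'   exist).
#' @return An object of class `run_manifest`.
#' @export
run_manifest <- function(result, files = character(0)) {
  stopifnot(inherits(result, "protocol_result"))
  if (length(files) > 0 && !all(file.exists(files)))
    stop("all recorded output files must exist")
  stages <- lapply(result$stages, function(st)
    list(duration = st$stage$duration, A = st$stage$forcing$A,
         T = st$stage$forcing$T, label = st$report$label,
         dominant_k = st$report$dominant_k))
  structure(list(config_hash = config_hash(result$config),
                 seed = result$config$seed,
                 version = as.character(utils::packageVersion("turingforce")),
                 stages = stages, files = files),
            class = "run_manifest")
}

# md5 of the canonical (recursively key-sorted) JSON serialization
config_hash <- function(config) {
  canonical <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x)) && any(names(x) != ""))
        x <- x[order(names(x))]
      lapply(x, canonical)
    } else x
  }
  p <- config$params
  flat <- list(a = p$a, b = p$b, sigma = p$sigma, c = p$c, dx = config$dx,
               nx = config$nx, ny = config$ny, dt = config$dt,
               noise_sd = config$noise_sd, seed = config$seed,
               snapshot_interval = config$snapshot_interval,
               stages = lapply(config$stages, function(st)
                 list(A = st$forcing$A, T = st$forcing$T,
                      duration = st$duration)))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(canonical(flat), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
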