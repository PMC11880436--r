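# Fixtures, configuration, experiment dispatch and result I/O: the plumbing
# that ties the kernel/synapse/network/ladder/unit modules into reproducible
# desk-scale experiments.

#' Generate a toy classification task
#'
#' Deterministic Gaussian-blob task standing in for MNIST at desk scale:
#' each class has a "one-hot-ish" center (a distinct block of features
#' raised to a high level, the rest low), isotropic Gaussian noise, values
#' clipped to [0, 1] to match the clip activations of the energy network.
#' Classes are stratified (counts equal to within one example) and the
#' whole dataset regenerates bit-identically from `(parameters, seed)`.
#'
#' @param n_classes Number of classes (<= `n_features`).
#' @param n_features Feature dimension.
#' @param n_train,n_test Split sizes.
#' @param noise Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @param center_lo,center_hi Background and active-block feature levels.
#'
#' @return A tibble with columns `set` ("train"/"test"), integer `label`
#'   (1-based) and features `x1..xp`; attribute `"centers"` holds the
#'   class-center matrix.
#' @export
generate_toy_task <- function(n_classes = 4L, n_features = 16L,
                              n_train = 200L, n_test = 80L, noise = 0.05,
                              seed = 1L, center_lo = 0.1, center_hi = 0.9) {
  if (n_classes > n_features || n_classes < 2L) {
    stop("need 2 <= n_classes <= n_features", call. = FALSE)
  }
  if (n_train < n_classes || n_test < 0) {
    stop("degenerate split sizes", call. = FALSE)
  }
  block <- floor(n_features / n_classes)
  centers <- matrix(center_lo, n_classes, n_features)
  for (cl in seq_len(n_classes)) {
    cols <- ((cl - 1L) * block + 1L):(cl * block)
    centers[cl, cols] <- center_hi
  }
  make_split <- function(n_total, set) {
    # stratified: class c gets floor(n/K) + (c <= n mod K) examples
    counts <- rep(n_total %/% n_classes, n_classes) +
      (seq_len(n_classes) <= n_total %% n_classes)
    labels <- rep(seq_len(n_classes), times = counts)
    X <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(length(labels) * n_features, sd = noise),
             ncol = n_features)
    X <- pmin(pmax(X, 0), 1)
    colnames(X) <- paste0("x", seq_len(n_features))
    dplyr::bind_cols(tibble::tibble(set = set, label = labels),
                     tibble::as_tibble(X))
  }
  out <- .with_seed(seed, {
    dplyr::bind_rows(make_split(n_train, "train"), make_split(n_test, "test"))
  })
  attr(out, "centers") <- centers
  attr(out, "params") <- list(n_classes = n_classes, n_features = n_features,
                              n_train = n_train, n_test = n_test,
                              noise = noise, seed = seed)
  out
}

#' Extract feature matrix and labels from a task tibble
#'
#' @param task A [generate_toy_task()] tibble (or any tibble with `set`,
#'   `label` and feature columns).
#' @param set Which split to extract.
#' @return List with matrix `x` and integer labels `y` — the input format
#'   of [train_tcl()].
#' @export
task_matrices <- function(task, set = c("train", "test")) {
  set <- match.arg(set)
  d <- dplyr::filter(task, .data$set == !!set)
  feats <- grep("^x\\d+$", names(d), value = TRUE)
  list(x = as.matrix(d[, feats]), y = as.integer(d$label))
}

#' Read an IDX-format array (MNIST container)
#'
#' Parses the big-endian IDX format: magic bytes `00 00 <type> <ndim>`,
#' `ndim` 32-bit dimensions, then the data. Supports the unsigned-byte type
#' (0x08) used by MNIST images and labels. Image grayscale values are
#' scaled to [0, 1] (0 -> 0.0, 255 -> 1.0).
#'
#' @param path Path to an IDX file.
#' @param scale Divide byte data by 255 (set `FALSE` for label files).
#' @return For 1-d files an integer vector; for n-d files a numeric matrix
#'   with one row per leading-dimension entry (images flattened row-wise).
#' @export
read_idx <- function(path, scale = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 4L, size = 1L, signed = FALSE)
  if (length(magic) < 4L || magic[1] != 0L || magic[2] != 0L) {
    stop("not an IDX file: bad magic number", call. = FALSE)
  }
  type <- magic[3]; ndim <- magic[4]
  if (type != 0x08) {
    stop(sprintf("unsupported IDX data type 0x%02x (only ubyte supported)",
                 type), call. = FALSE)
  }
  dims <- readBin(con, "integer", n = ndim, size = 4L, endian = "big")
  if (length(dims) < ndim || any(dims <= 0)) {
    stop("truncated or invalid IDX header", call. = FALSE)
  }
  n_items <- prod(dims)
  raw_data <- readBin(con, "integer", n = n_items, size = 1L, signed = FALSE)
  if (length(raw_data) < n_items) {
    stop("truncated IDX data section", call. = FALSE)
  }
  if (ndim == 1L) {
    return(as.integer(raw_data))
  }
  scale <- scale %||% TRUE
  M <- matrix(raw_data, nrow = dims[1], ncol = prod(dims[-1]), byrow = TRUE)
  if (scale) M / 255 else M
}

#' Write an IDX-format array
#'
#' Inverse of [read_idx()]; used to build fixtures and to round-trip data.
#'
#' @param data Integer vector (labels) or matrix of values in 0..255 with
#'   one row per item (images, written with dimensions `c(nrow, dims...)`).
#' @param path Output path.
#' @param dims Trailing dimensions for matrix data (default: `ncol(data)`).
#' @return `path`, invisibly.
#' @export
write_idx <- function(data, path, dims = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (is.matrix(data)) {
    dims <- c(nrow(data), dims %||% ncol(data))
    vals <- as.integer(t(data))
  } else {
    dims <- length(data)
    vals <- as.integer(data)
  }
  if (any(vals < 0 | vals > 255)) {
    stop("IDX ubyte data must lie in 0..255", call. = FALSE)
  }
  writeBin(as.raw(c(0, 0, 0x08, length(dims))), con)
  writeBin(as.integer(dims), con, size = 4L, endian = "big")
  writeBin(as.raw(vals), con)
  invisible(path)
}

#' Load an MNIST-style image/label pair
#'
#' @param image_path,label_path IDX files for images and labels.
#' @return List with matrix `x` (rows = images, scaled to [0,1]) and
#'   integer labels `y` shifted to 1-based classes.
#' @export
read_idx_dataset <- function(image_path, label_path) {
  x <- read_idx(image_path)
  y <- read_idx(label_path)
  if (nrow(x) != length(y)) {
    stop("image and label files disagree on the number of items",
         call. = FALSE)
  }
  list(x = x, y = as.integer(y) + 1L)
}

# ---- experiment configuration -------------------------------------------

.known_blocks <- c("kernel", "protocol", "synapse", "schedule", "network",
                   "task", "ladder", "units", "sweep")

#' Read and validate an experiment configuration
#'
#' JSON configuration with named parameter blocks (`kernel`, `protocol`,
#' `synapse`, `schedule`, `network`, `task`, `ladder`, `units`, `sweep`)
#' plus a `pipeline` name and a `seed`. Unknown top-level keys are
#' rejected; the configuration round-trips losslessly through JSON.
#'
#' @param path Path to a JSON file, or a named list already in memory.
#' @return The validated configuration list (class `tcl_config`).
#' @export
read_experiment_config <- function(path) {
  cfg <- if (is.character(path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    path
  }
  extra <- setdiff(names(cfg), c(.known_blocks, "pipeline", "seed", "out_dir"))
  if (length(extra)) {
    stop("unknown configuration keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$pipeline)) stop("configuration lacks a pipeline", call. = FALSE)
  structure(cfg, class = c("tcl_config", "list"))
}

#' Run a configured experiment
#'
#' Dispatches on `config$pipeline`:
#' \describe{
#'   \item{`synapse-sweep` / `offset-sweep`}{amplitude sweep of the
#'     per-cycle update; writes `sweep.csv` (columns `A`,
#'     `delta_w_over_eps`) and a `summary.csv` with the fitted slope,
#'     offset and dynamic range.}
#'   \item{`train`}{toy-task (or IDX) network training; writes per-epoch
#'     `metrics.csv`.}
#'   \item{`ladder`}{dissipation-offset curve over a `gamma` grid; writes
#'     `ladder.csv` (columns `gamma`, `sigma`, `kernel_area`, `offset`,
#'     `normalized_offset`).}
#'   \item{`units`}{simulates a physical unit on a sawtooth; writes
#'     `trace.csv` (columns `t`, `s`, `u`).}
#'   \item{`kernels`}{builds a kernel; writes it as `kernel.csv`.}
#' }
#' Every run writes `manifest.json` (pipeline, full configuration, seed,
#' package version, configuration hash, per-stage status) sufficient to
#' reproduce it exactly; all randomness flows from `config$seed`.
#'
#' @param config A [read_experiment_config()] result, path, or list.
#' @param out_dir Output directory (created if missing; default
#'   `config$out_dir`).
#' @param seed Overrides `config$seed` when given.
#' @return Invisibly, a list with the result object(s), the file paths and
#'   the manifest.
#' @export
run_experiment <- function(config, out_dir = NULL, seed = NULL) {
  if (!inherits(config, "tcl_config")) config <- read_experiment_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stop("no output directory given",
                                                   call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  need <- function(block) {
    if (is.null(config[[block]])) {
      stop(sprintf("configuration is missing the required '%s' block", block),
           call. = FALSE)
    }
    config[[block]]
  }
  status <- "ok"
  files <- character()
  result <- tryCatch({
    switch(
      config$pipeline,
      "synapse-sweep" = ,
      "offset-sweep" = {
        kc <- need("kernel"); pc <- need("protocol"); sc <- need("synapse")
        sw <- need("sweep")
        kern <- .config_kernel(kc)
        template <- sawtooth_protocol(
          amplitude = max(sw$amplitudes), s_mean = pc$s_mean %||% 0,
          tau_f = pc$tau_f, tau_s = pc$tau_s, dt = kern$dt)
        theta <- sc$theta_g %||%
          choose_threshold(kern, pc$tau_f, pc$tau_s, max(sw$amplitudes),
                           s_mean = pc$s_mean %||% 0)
        cfg <- synapse_config(kern, theta_g = theta,
                              epsilon = sc$epsilon %||% 1)
        sweep <- amplitude_sweep(cfg, template, sort(sw$amplitudes))
        files <- c(sweep = file.path(out_dir, "sweep.csv"),
                   summary = file.path(out_dir, "summary.csv"))
        write_sweep_csv(sweep, files[["sweep"]])
        readr::write_csv(glance(sweep), files[["summary"]])
        sweep
      },
      "train" = {
        tk <- need("task"); nw <- need("network"); sch <- need("schedule")
        sc <- need("synapse"); kc <- need("kernel")
        task <- generate_toy_task(
          n_classes = tk$n_classes %||% 4L,
          n_features = tk$n_features %||% 16L,
          n_train = tk$n_train %||% 200L, n_test = tk$n_test %||% 80L,
          noise = tk$noise %||% 0.05, seed = seed)
        kern <- .config_kernel(kc)
        net <- energy_network(tk$n_features %||% 16L,
                              nw$n_hidden %||% 8L,
                              tk$n_classes %||% 4L, seed = seed)
        schedule <- nudge_schedule(
          beta_max = sch$beta_max %||% 0.5, tau_f = sch$tau_f %||% 0.1,
          tau_s = sch$tau_s %||% 0.9,
          steps_per_cycle = sch$steps_per_cycle %||% 60L,
          cycles_per_example = sch$cycles_per_example %||% 1L)
        cfg <- synapse_config(kern, theta_g = sc$theta_g %||% 0.02,
                              epsilon = sc$epsilon %||% 0.02)
        fit <- train_tcl(net, task_matrices(task, "train"), schedule, cfg,
                         epochs = nw$epochs %||% 20L, seed = seed,
                         test = task_matrices(task, "test"))
        files <- c(metrics = file.path(out_dir, "metrics.csv"))
        readr::write_csv(fit$metrics, files[["metrics"]])
        fit
      },
      "ladder" = {
        lc <- need("ladder")
        curve <- dissipation_offset_curve(
          gammas = lc$gammas, m = lc$m %||% 5L,
          base_rate = lc$base_rate %||% 1,
          coupling_strength = lc$coupling_strength %||% 1,
          s_mean = lc$s_mean %||% 1,
          tau_f = lc$tau_f %||% 10, tau_s = lc$tau_s %||% 100)
        files <- c(ladder = file.path(out_dir, "ladder.csv"))
        readr::write_csv(curve, files[["ladder"]])
        curve
      },
      "units" = {
        uc <- need("units"); pc <- need("protocol")
        params <- .config_unit(uc)
        protocol <- sawtooth_protocol(
          amplitude = pc$amplitude, s_mean = pc$s_mean %||% 0,
          tau_f = pc$tau_f, tau_s = pc$tau_s, dt = pc$dt %||% 1e-3)
        tr <- .protocol_trace(protocol)
        sim <- switch(uc$type,
          "integral_feedback" = simulate_integral_feedback(params, tr$s,
                                                           protocol$dt),
          "autoregulation" = simulate_autoregulation(params, tr$s,
                                                     protocol$dt),
          "maxwell" = simulate_maxwell(params, tr$s, protocol$dt),
          "rc" = simulate_rc(params, tr$s, protocol$dt))
        files <- c(trace = file.path(out_dir, "trace.csv"))
        readr::write_csv(sim[, c("t", "s", "u")], files[["trace"]])
        sim
      },
      "kernels" = {
        kern <- .config_kernel(need("kernel"))
        files <- c(kernel = file.path(out_dir, "kernel.csv"))
        write_kernel_csv(kern, files[["kernel"]])
        kern
      },
      stop("unknown pipeline '", config$pipeline, "'", call. = FALSE)
    )
  }, error = function(e) {
    status <<- conditionMessage(e)
    NULL
  })
  manifest <- list(
    pipeline = config$pipeline,
    seed = seed,
    status = status,
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("tempocon")),
    files = as.list(files)
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (status != "ok") {
    stop("experiment failed (recorded in manifest): ", status, call. = FALSE)
  }
  invisible(list(result = result, files = files, manifest = manifest,
                 manifest_path = manifest_path))
}

.config_kernel <- function(kc) {
  switch(kc$family %||% "biphasic",
    "biphasic" = make_biphasic_kernel(kc$tau_K, kc$target_area %||% 0,
                                      dt = kc$dt %||% (kc$tau_K / 50),
                                      t_max = kc$t_max %||% (10 * kc$tau_K)),
    "sine" = make_sine_kernel(kc$tau_K, dt = kc$dt %||% (kc$tau_K / 50),
                              unit_gain = kc$unit_gain %||% TRUE),
    "feedback" = make_feedback_kernel(kc$tau_u, kc$tau_m, kc$k,
                                      dt = kc$dt, t_max = kc$t_max),
    stop("unknown kernel family '", kc$family, "'", call. = FALSE)
  )
}

.config_unit <- function(uc) {
  switch(uc$type,
    "integral_feedback" = integral_feedback_params(
      tau_u = uc$tau_u %||% 1, tau_m = uc$tau_m %||% 1, k = uc$k %||% 1,
      u0 = uc$u0 %||% 0),
    "autoregulation" = autoregulation_params(
      tau_u = uc$tau_u %||% 1, tau_m = uc$tau_m %||% 1,
      tau_l = uc$tau_l %||% 10, k_a = uc$k_a %||% 1, k_i = uc$k_i %||% 1,
      u_s = uc$u_s %||% 0.01, u0 = uc$u0 %||% 1),
    "maxwell" = maxwell_params(k_spring = uc$k_spring %||% 1,
                               eta_dash = uc$eta_dash %||% 1),
    "rc" = rc_params(R = uc$R %||% 1, C = uc$C %||% 1),
    stop("unknown unit type '", uc$type, "'", call. = FALSE)
  )
}
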