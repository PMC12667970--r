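#' Serialisation of package objects
#'
#' Small structured objects (networks, input specs, coding bases, trial
#' biases, error axes) are written as JSON with full numeric precision, so
#' they are portable and diffable; activity tensors, whose rate arrays can
#' run to millions of values, are written as RDS. All writers record the
#' object class and array dimensions so reading restores the object exactly
#' (numeric fields round-trip to better than 1e-12).
#'
#' @name latentloop_io
NULL

mat_to_json <- function(m) list(data = as.numeric(m), dim = dim(m))
json_to_mat <- function(j) {
  m <- matrix(j$data, j$dim[1], j$dim[2])
  m
}

#' Write a low-rank network (with optional input spec) to JSON
#' @param net a \code{\link{lowrank_network}}.
#' @param path output file.
#' @param spec optional \code{\link{input_spec}} stored alongside.
#' @export
write_network <- function(net, path, spec = NULL) {
  obj <- list(class = "lowrank_network", U = mat_to_json(net$U),
              A = mat_to_json(net$A), rmax = net$rmax, tau = net$tau,
              C = net$C)
  if (!is.null(spec))
    obj$spec <- list(i_low = spec$i_low, i_high = spec$i_high,
                     i_go = spec$i_go, lick_left = spec$lick_left,
                     lick_right = spec$lick_right,
                     tone_windows = mat_to_json(spec$tone_windows),
                     go_window = spec$go_window)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a network written by \code{\link{write_network}}
#' @param path JSON file.
#' @return list with \code{network} and (possibly NULL) \code{spec}.
#' @export
read_network <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$class, "lowrank_network"))
    stop("file ", path, " does not contain a lowrank_network")
  net <- lowrank_network(json_to_mat(j$U), json_to_mat(j$A), j$rmax,
                         tau = j$tau, C = j$C, orth_tol = Inf)
  spec <- NULL
  if (!is.null(j$spec))
    spec <- input_spec(net$P, net$N, i_low = j$spec$i_low,
                       i_high = j$spec$i_high, i_go = j$spec$i_go,
                       lick_left = j$spec$lick_left,
                       lick_right = j$spec$lick_right,
                       tone_windows = json_to_mat(j$spec$tone_windows),
                       go_window = j$spec$go_window)
  list(network = net, spec = spec)
}

#' Write a coding basis to JSON
#' @param basis a \code{coding_basis}.
#' @param path output file.
#' @export
write_coding_basis <- function(basis, path) {
  obj <- list(class = "coding_basis", vectors = mat_to_json(basis$vectors),
              windows = basis$windows, source = basis$source)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a coding basis written by \code{\link{write_coding_basis}}
#' @param path JSON file.
#' @return a \code{coding_basis}.
#' @export
read_coding_basis <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$class, "coding_basis"))
    stop("file ", path, " does not contain a coding_basis")
  structure(list(vectors = json_to_mat(j$vectors),
                 windows = lapply(j$windows, as.numeric),
                 source = j$source),
            class = "coding_basis")
}

#' Write an activity tensor to RDS
#' @param tensor an \code{activity_tensor}.
#' @param path output file.
#' @export
write_activity_tensor <- function(tensor, path) {
  saveRDS(tensor, path)
  invisible(path)
}

#' Read an activity tensor written by \code{\link{write_activity_tensor}}
#' @param path RDS file.
#' @return an \code{activity_tensor}.
#' @export
read_activity_tensor <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "activity_tensor"))
    stop("file ", path, " does not contain an activity_tensor")
  obj
}

#' Run a staged analysis pipeline
#'
#' Executes the named stages (\code{synth}, \code{coding_axes},
#' \code{fit_avg}, \code{spectral}, \code{attractors}) with the parameters
#' in \code{config}, writing each stage's artifact plus a JSON manifest
#' recording the configuration, seed, package version and output file
#' hashes.
#'
#' @param config list with fields \code{out_dir}, \code{seed}, and optional
#'   stage parameter blocks \code{synth} (N, P, C, trials, dt),
#'   \code{fit} (P, iterations).
#' @param stages character vector of stages to run, in order.
#' @return invisible list of artifact paths.
#' @export
run_pipeline <- function(config,
                         stages = c("synth", "coding_axes", "fit_avg",
                                    "spectral")) {
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  paths <- list()
  sy <- config$synth
  if (is.null(sy)) sy <- list()
  N <- sy$N %||% 60; P <- sy$P %||% 5; C <- sy$C %||% 3
  trials <- sy$trials %||% 30; dt <- sy$dt %||% 0.01

  tensor <- NULL; basis <- NULL; fit <- NULL
  for (st in stages) {
    if (st == "synth") {
      gt <- make_ground_truth(N, P, C, seed = seed)
      tensor <- generate_recordings(gt, trials, dt = dt)
      paths$tensor <- file.path(config$out_dir, "recordings.rds")
      write_activity_tensor(tensor, paths$tensor)
    } else if (st == "coding_axes") {
      if (is.null(tensor)) tensor <- read_activity_tensor(
        file.path(config$out_dir, "recordings.rds"))
      basis <- estimate_coding_basis(tensor)
      paths$basis <- file.path(config$out_dir, "coding_basis.json")
      write_coding_basis(basis, paths$basis)
    } else if (st == "fit_avg") {
      if (is.null(tensor) || is.null(basis))
        stop("fit_avg requires the synth and coding_axes artifacts")
      ft <- config$fit
      if (is.null(ft)) ft <- list()
      fit <- train_condition_averaged(
        tensor, basis, P = ft$P %||% P,
        opt = optimizer_config(max_iterations = ft$iterations %||% 1000,
                               seed = seed))
      paths$network <- file.path(config$out_dir, "network.json")
      write_network(fit$network, paths$network, spec = fit$spec)
      utils::write.csv(fit$log,
                       file.path(config$out_dir, "training_log.csv"),
                       row.names = FALSE)
    } else if (st == "spectral") {
      if (is.null(fit)) fit <- read_network(
        file.path(config$out_dir, "network.json"))
      A <- if (inherits(fit, "lowrank_fit")) fit$network$A else fit$network$A
      sm <- schur_modes(A)
      rep <- list(henrici = henrici_index(A),
                  eigenvalues_real = Re(sm$eig),
                  eigenvalues_imag = Im(sm$eig),
                  n_negative = sm$n_negative)
      paths$spectral <- file.path(config$out_dir, "spectral.json")
      jsonlite::write_json(rep, paths$spectral, auto_unbox = TRUE,
                           digits = NA)
    } else stop("unknown stage: ", st)
  }
  manifest <- list(seed = seed, config = config[setdiff(names(config), "")],
                   stages = stages,
                   package_version = as.character(utils::packageVersion("latentloop")),
                   files = lapply(paths, function(p)
                     list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
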