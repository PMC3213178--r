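#' Write an ensemble to disk
#'
#' Writes a parameters-by-members CSV matrix (`ensemble.csv`, row names =
#' parameter names in `[rate constants, initial conditions]` order) plus a
#' JSON sidecar (`ensemble.json`) with ranks, per-objective errors, fold
#' ids, seed, objective ids and a hash of the run configuration.
#'
#' @param ensemble a `poets_archive`
#' @param dir output directory (created if needed)
#' @return the CSV path, invisibly
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  M <- archive_param_matrix(ensemble)
  p1 <- ensemble$entries$params[[1]]
  rownames(M) <- c(names(p1$k), names(p1$x0))
  colnames(M) <- paste0("member_", ensemble$entries$member)
  csv <- file.path(dir, "ensemble.csv")
  write.csv(M, csv, row.names = TRUE)
  sidecar <- list(
    ranks = ensemble$entries$rank,
    fold_ids = ensemble$entries$fold_id,
    errors = lapply(ensemble$entries$errors, unname),
    objective_ids = ensemble$objective_ids,
    seed = ensemble$seed,
    n_rate_constants = length(p1$k),
    config_hash = config_hash(ensemble$config),
    config = unclass(ensemble$config)
  )
  jsonlite::write_json(sidecar, file.path(dir, "ensemble.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv)
}

#' Read an ensemble from disk
#'
#' Accepts either a directory written by [write_ensemble()] (CSV matrix +
#' JSON sidecar) or a directory of flat parameter files — one whitespace- or
#' newline-separated numeric vector per file, in `[rate constants, initial
#' conditions]` order — the format ensemble members are commonly shipped in.
#'
#' @param path ensemble directory
#' @param net the `rxn_network` the parameters belong to
#' @return a `poets_archive` (ranks/errors `NA` when only flat files are
#'   available)
#' @export
read_ensemble <- function(path, net) {
  if (!dir.exists(path)) abort(paste0("ensemble directory not found: ", path))
  csv <- file.path(path, "ensemble.csv")
  n_par <- nrow(net$reactions) + nrow(net$species)
  if (file.exists(csv)) {
    M <- as.matrix(read.csv(csv, row.names = 1, check.names = FALSE))
    if (nrow(M) != n_par) {
      abort(paste0("ensemble has ", nrow(M), " parameters; network needs ",
                   n_par))
    }
    params <- lapply(seq_len(ncol(M)), function(j) as_param_vec(M[, j], net))
    side_path <- file.path(path, "ensemble.json")
    if (file.exists(side_path)) {
      side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
      errors <- if (is.matrix(side$errors)) {
        lapply(seq_len(nrow(side$errors)), function(i) {
          setNames(side$errors[i, ], side$objective_ids)
        })
      } else {
        lapply(side$errors, function(e) setNames(unlist(e), side$objective_ids))
      }
      entries <- tibble(member = seq_len(ncol(M)),
                        iteration = NA_integer_,
                        fold_id = side$fold_ids,
                        rank = side$ranks,
                        errors = errors,
                        params = params)
      return(structure(list(entries = entries, trace = NULL,
                            objective_ids = side$objective_ids,
                            config = side$config, seed = side$seed),
                       class = "poets_archive"))
    }
  } else {
    files <- sort(list.files(path, full.names = TRUE))
    files <- files[!grepl("\\.json$", files)]
    if (!length(files)) abort(paste0("no ensemble files found in ", path))
    params <- lapply(files, function(f) {
      v <- scan(f, quiet = TRUE)
      if (length(v) != n_par) {
        abort(paste0(basename(f), " has ", length(v),
                     " values; network needs ", n_par))
      }
      as_param_vec(v, net)
    })
  }
  entries <- tibble(member = seq_along(params),
                    iteration = NA_integer_, fold_id = NA_integer_,
                    rank = NA_integer_,
                    errors = rep(list(NULL), length(params)),
                    params = params)
  structure(list(entries = entries, trace = NULL, objective_ids = NULL,
                 config = NULL, seed = NA_integer_),
            class = "poets_archive")
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # small stable rolling hash; provenance tag, not cryptographic
  h <- 0
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}
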