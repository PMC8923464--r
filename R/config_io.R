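# Reproducibility plumbing: seeded evaluation, per-module seed streams,
# YAML configuration, run manifests, and tidy result export.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so seeded helpers never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive an independent sub-seed from a global seed and a stream label
#'
#' Expands one user-supplied seed into per-module streams so that, e.g., the
#' noise draws and the rove draws of one run are reproducible yet decoupled.
#' The result is always a valid 32-bit integer seed.
#'
#' @param seed Global integer seed.
#' @param label Character stream label (or an integer index).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  h <- if (is.character(label)) sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
       else as.numeric(label)
  as.integer((as.numeric(seed) * 1000003 + h * 7919 + 12345) %% 2147483647)
}

#' Build a run manifest describing a simulation run
#'
#' @param seed Global seed used.
#' @param preset Grid preset name.
#' @param config Front-end configuration (list).
#' @param extra Optional named list of additional fields.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(seed, preset, config, extra = list()) {
  structure(c(list(package = "anpitch",
                   version = as.character(utils::packageVersion("anpitch")),
                   seed = seed, preset = preset,
                   config = unclass(config),
                   timestamp = format(Sys.time(), tz = "UTC")),
              extra),
            class = "run_manifest")
}

#' Write a run manifest to JSON
#' @param manifest A `run_manifest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a front-end configuration from YAML
#'
#' Unknown keys are rejected with a message naming the offending key.
#'
#' @param path YAML file path.
#' @return A `frontend_config`.
#' @export
read_frontend_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(frontend_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown front-end configuration key(s): ",
         paste(bad, collapse = ", "))
  }
  do.call(frontend_config, vals)
}

#' Write a front-end configuration to YAML
#' @param config A `frontend_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frontend_config <- function(config, path) {
  out <- unclass(config)
  # yaml drops names of atomic vectors; store per-class values as maps
  out$spont <- as.list(out$spont)
  out$class_xs_shift_db <- as.list(out$class_xs_shift_db)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a threshold-curve (or any tidy) result table as CSV
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
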