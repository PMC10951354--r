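# Structured-text configuration (YAML), trace/metric serialisation and the
# run manifest. The schema is deliberately flat: one document describes one
# named scenario plus parameter overrides.

config_schema <- function() {
  list(
    schema_version = function(v) {
      if (!identical(as.integer(v), 1L)) "must be 1"
    },
    scenario = function(v) {
      if (!is.character(v) || length(v) != 1 ||
          !v %in% list_scenarios()) {
        paste0("must be one of: ", paste(list_scenarios(), collapse = ", "))
      }
    },
    contextualise = function(v) {
      if (!is.logical(v) || length(v) != 1 || is.na(v)) "must be true/false"
    },
    seed = function(v) {
      if (!is.numeric(v) || length(v) != 1 || v != round(v)) {
        "must be an integer"
      }
    },
    dt = function(v) {
      if (!is.numeric(v) || length(v) != 1 || v <= 0) "must be > 0"
    },
    duration = function(v) {
      if (!is.numeric(v) || length(v) != 1 || v <= 0) "must be > 0"
    },
    transient_frac = function(v) {
      if (!is.numeric(v) || v < 0 || v >= 1) "must lie in [0, 1)"
    },
    model = list(
      lambda_v = function(v) if (!is.numeric(v) || v <= 0) "must be > 0",
      kappa = function(v) if (!is.numeric(v) || v < 0) "must be >= 0"
    ),
    process = list(
      k = function(v) if (!is.numeric(v) || v < 0) "must be >= 0",
      sigma = function(v) if (!is.numeric(v) || v < 0) "must be >= 0",
      sigma_w = function(v) if (!is.numeric(v) || v < 0) "must be >= 0",
      sigma_r = function(v) if (!is.numeric(v) || v < 0) "must be >= 0",
      omega = function(v) if (!is.numeric(v)) "must be numeric",
      k_cb = function(v) if (!is.numeric(v) || v < 0) "must be >= 0",
      k_intr = function(v) if (!is.numeric(v) || v < 0) "must be >= 0"
    )
  )
}

config_defaults <- function() {
  list(schema_version = 1L, contextualise = TRUE, seed = 1L)
}

validate_block <- function(doc, schema, path = character()) {
  unknown <- setdiff(names(doc), names(schema))
  if (length(unknown) > 0) {
    stop("schema violation: unknown key '",
         paste(c(path, unknown[1]), collapse = "."), "'", call. = FALSE)
  }
  for (key in names(doc)) {
    rule <- schema[[key]]
    here <- paste(c(path, key), collapse = ".")
    if (is.list(rule)) {
      if (!is.list(doc[[key]])) {
        stop("schema violation: key '", here, "' must be a mapping",
             call. = FALSE)
      }
      validate_block(doc[[key]], rule, c(path, key))
    } else {
      msg <- rule(doc[[key]])
      if (!is.null(msg)) {
        stop("schema violation: key '", here, "' ", msg, call. = FALSE)
      }
    }
  }
  invisible(doc)
}

normalise_config <- function(doc) {
  validate_block(doc, config_schema())
  if (is.null(doc$scenario)) {
    stop("schema violation: key 'scenario' is required", call. = FALSE)
  }
  doc <- utils::modifyList(config_defaults(), doc)
  doc$schema_version <- as.integer(doc$schema_version)
  doc$seed <- as.integer(doc$seed)
  # stable key order so semantically identical documents hash identically
  top <- c("schema_version", "scenario", "contextualise", "seed", "dt",
           "duration", "transient_frac", "model", "process")
  doc <- doc[intersect(top, names(doc))]
  for (blk in c("model", "process")) {
    if (!is.null(doc[[blk]])) doc[[blk]] <- doc[[blk]][order(names(doc[[blk]]))]
  }
  structure(doc, class = "config_document")
}

#' Load and validate a scenario configuration
#'
#' Reads a YAML configuration document, rejects unknown keys, checks every
#' constraint (naming the offending key) and applies defaults. The
#' normalised document round-trips losslessly through [write_config()].
#'
#' @param path path to a YAML file; must at least name a \code{scenario}.
#' @return An object of class \code{"config_document"} (a named list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration error: file not found: ", path, call. = FALSE)
  }
  doc <- yaml::read_yaml(path)
  if (!is.list(doc)) {
    stop("parse error: ", path, " does not contain a YAML mapping",
         call. = FALSE)
  }
  normalise_config(doc)
}

#' @rdname load_config
#' @param config a \code{"config_document"} (or a plain list, which is
#'   normalised first).
#' @export
write_config <- function(config, path) {
  if (!inherits(config, "config_document")) config <- normalise_config(config)
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Run a scenario described by a configuration document
#'
#' @param config a \code{"config_document"} from [load_config()].
#' @return A \code{"scenario_result"}.
#' @export
run_from_config <- function(config) {
  if (!inherits(config, "config_document")) config <- normalise_config(config)
  args <- list(contextualise = config$contextualise, seed = config$seed)
  for (nm in c("dt", "duration")) {
    if (!is.null(config[[nm]])) args[[nm]] <- config[[nm]]
  }
  if (!is.null(config$model$lambda_v)) args$lambda_v <- config$model$lambda_v
  if (!is.null(config$model$kappa)) args$kappa <- config$model$kappa
  p <- config$process
  if (config$scenario == "locomotion") {
    for (nm in c("omega", "sigma", "k_cb", "k_intr")) {
      if (!is.null(p[[nm]])) args[[nm]] <- p[[nm]]
    }
  } else {
    if (!is.null(p$k)) args$k <- p$k
    if (!is.null(p$sigma)) args$sigma <- p$sigma
  }
  do.call(run_named_scenario, c(list(name = config$scenario), args))
}

#' Write / read a simulation trace as CSV
#'
#' One row per step with the documented column names; values are written
#' with round-trip (full) precision, so a read-back reproduces the
#' in-memory series bit-for-bit.
#'
#' @param trace a \code{"simulation_trace"} (any data.frame is accepted).
#' @param path output CSV path.
#' @return \code{write_trace()} returns \code{path} invisibly;
#'   \code{read_trace()} returns a data.frame.
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  # 17 significant digits: every double round-trips exactly
  chr <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  })
  out <- data.table::as.data.table(chr)
  data.table::setnames(out, names(df))
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  as.data.frame(data.table::fread(path, colClasses = "numeric"))
}

#' Manifest of a simulation run
#'
#' Provenance record serialised next to the metrics: scenario id, seed, a
#' deterministic hash of the normalised configuration, package version,
#' timestamp and output paths.
#'
#' @param result a \code{"scenario_result"}.
#' @param config the \code{"config_document"} that produced it (optional).
#' @param outputs named character vector/list of output paths.
#' @return A named list of class \code{"run_manifest"}.
#' @export
run_manifest <- function(result, config = NULL, outputs = list()) {
  structure(
    list(
      scenario = result$scenario,
      seed = result$condition$seed,
      config_hash = if (is.null(config)) NA_character_ else
        rlang::hash(unclass(normalise_config(unclass(config)))),
      package_version = as.character(utils::packageVersion("cerebsync")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      outputs = outputs
    ),
    class = "run_manifest"
  )
}

#' Write scenario metrics (and manifest) as JSON
#'
#' Every entry of the result's metrics map is written as a bare number at
#' full precision, alongside the condition labels and, if supplied, the run
#' manifest.
#'
#' @param result a \code{"scenario_result"}.
#' @param path output JSON path.
#' @param manifest optional [run_manifest()].
#' @return \code{path}, invisibly.
#' @export
write_metrics <- function(result, path, manifest = NULL) {
  payload <- list(
    scenario = result$scenario,
    condition = result$condition,
    metrics = result$metrics
  )
  if (!is.null(manifest)) payload$manifest <- unclass(manifest)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
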