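# Plain-text I/O: recordings as delimited matrices with a JSON sidecar,
# feature tables as CSV, fitted networks as JSON. Labels travel as the
# strings "alert"/"fatigue" in sidecars and manifests and are mapped to 0/1
# at load time, so the 0/1 convention cannot silently flip.

label_to_string <- function(label) {
  if (is.na(label)) return(NULL)
  if (label == 1L) "fatigue" else "alert"
}

string_to_label <- function(s) {
  if (is.null(s)) return(NA_integer_)
  if (!s %in% c("alert", "fatigue")) {
    stop("label string must be 'alert' or 'fatigue'")
  }
  if (s == "fatigue") 1L else 0L
}

#' Write a recording to disk
#'
#' Writes `<stem>.tsv` (channels in rows, tab-delimited, no header) and a
#' JSON sidecar `<stem>.json` holding rate, channel names, label string and
#' subject id.
#'
#' @param rec A [recording()].
#' @param stem Path prefix (without extension).
#' @return The sidecar path, invisibly.
#' @export
write_recording <- function(rec, stem) {
  stopifnot(inherits(rec, "Recording"))
  utils::write.table(rec$data, paste0(stem, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  side <- list(rate = rec$rate, channel_names = rec$channel_names,
               label = label_to_string(rec$label),
               subject_id = rec$subject_id, format_version = 1L)
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(stem, ".json"))
}

#' Read a recording from disk
#'
#' @param path Path to the `.tsv` matrix (channels in rows) or the path stem.
#' @param sidecar Path to the JSON sidecar; defaults to the `.tsv` path with
#'   extension swapped to `.json`.
#' @return A [recording()].
#' @export
read_recording <- function(path, sidecar = NULL) {
  stem <- sub("\\.tsv$", "", path)
  path <- paste0(stem, ".tsv")
  if (is.null(sidecar)) sidecar <- paste0(stem, ".json")
  if (!file.exists(path)) stop("recording matrix not found: ", path)
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  data <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(data) <- NULL
  if (!is.null(side$channel_names) &&
      length(side$channel_names) != nrow(data)) {
    stop(sprintf("sidecar lists %d channels but the matrix has %d rows",
                 length(side$channel_names), nrow(data)))
  }
  recording(data, side$rate, side$channel_names,
            string_to_label(side$label),
            if (is.null(side$subject_id)) "unknown" else side$subject_id)
}

#' Write a feature set
#'
#' Writes `<stem>.csv` (one row per epoch, feature columns then a final
#' `label` column) and `<stem>.json` holding normalization statistics,
#' pipeline parameters and per-epoch variance ratios.
#'
#' @param fs A `FeatureSet`.
#' @param stem Path prefix.
#' @return The CSV path, invisibly.
#' @export
write_features <- function(fs, stem) {
  stopifnot(inherits(fs, "FeatureSet"))
  df <- as.data.frame(fs$X)
  names(df) <- sprintf("f%04d", seq_len(ncol(fs$X)))
  df$label <- fs$y
  utils::write.table(df, paste0(stem, ".csv"), sep = ",",
                     row.names = FALSE, col.names = TRUE, qmethod = "double")
  meta <- list(norm_stats = fs$norm_stats, params = fs$params,
               variance_ratios = fs$variance_ratios, format_version = 1L)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paste0(stem, ".csv"))
}

#' Read a feature set written by [write_features()]
#'
#' @param stem Path prefix (or the `.csv` path).
#' @return A `FeatureSet`.
#' @export
read_features <- function(stem) {
  stem <- sub("\\.csv$", "", stem)
  df <- utils::read.table(paste0(stem, ".csv"), sep = ",", header = TRUE)
  meta_path <- paste0(stem, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  X <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  dimnames(X) <- NULL
  ns <- meta$norm_stats
  if (!is.null(ns)) ns <- list(method = ns$method, center = ns$center,
                               scale = ns$scale)
  structure(
    list(X = X, y = as.integer(df$label),
         variance_ratios = meta$variance_ratios,
         norm_stats = ns, params = meta$params),
    class = "FeatureSet"
  )
}

#' Serialize a fitted network to JSON
#'
#' Full double precision; the file round-trips predictions exactly (to
#' floating-point parsing precision).
#'
#' @param net An `RBFNetwork`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(net, path) {
  stopifnot(inherits(net, "RBFNetwork"))
  obj <- list(format_version = net$format_version,
              rho = net$rho, lambda = net$lambda, beta = net$beta,
              centers = net$centers, theta = net$theta,
              selected_indices = net$selected_indices,
              pipeline_params = net$pipeline_params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Load a network saved by [save_model()]
#'
#' A model without frozen pipeline parameters loads with a warning: it can
#' score pre-built feature matrices but must not be applied to raw
#' recordings.
#'
#' @param path Path to the JSON model file.
#' @return An `RBFNetwork`.
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("cannot parse model file (truncated or corrupt): ",
                         conditionMessage(e))
                  })
  need <- c("rho", "centers", "theta")
  if (!all(need %in% names(obj))) {
    stop("model file is missing required fields: ",
         paste(setdiff(need, names(obj)), collapse = ", "))
  }
  if (!is.null(obj$format_version) && obj$format_version > 1L) {
    warning("model was written by a newer format version; ",
            "attempting to read anyway")
  }
  if (is.null(obj$pipeline_params)) {
    warning("model carries no pipeline parameters; ",
            "do not apply it to raw recordings")
  }
  centers <- obj$centers
  if (!is.matrix(centers)) centers <- matrix(centers, nrow = 1L)
  rbf_network(centers, obj$rho, obj$theta, obj$selected_indices,
              if (is.null(obj$lambda)) NA_real_ else obj$lambda,
              if (is.null(obj$beta)) NA_real_ else obj$beta,
              obj$pipeline_params)
}
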