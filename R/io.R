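#' Read a landmark table
#'
#' Two dialects are supported. `"long"` is the package's canonical CSV:
#' one row per (frame, landmark) with columns `frame_id`, `animal_id`,
#' `experiment_id`, `condition`, `phase_time_s`, `observer_id`,
#' `excluded`, `exclusion_reason`, `side`, `landmark`, `x`, `y` and
#' optional `confidence`. `"dlc"` is the DeepLabCut-style wide CSV with
#' three header rows (scorer / bodypart / x,y,likelihood); body-part
#' names are translated to the canonical vocabulary through `mapping`.
#' Landmarks whose confidence falls below `confidence_threshold` are
#' dropped (treated as missing for that frame).
#'
#' @param path CSV file.
#' @param dialect `"long"` or `"dlc"`.
#' @param mapping Named character vector, body-part name -> canonical
#'   landmark name (dlc dialect; unmapped body parts are reported and
#'   skipped).
#' @param confidence_threshold Minimum confidence to keep a landmark.
#' @param animal_id,condition Metadata to attach when the dlc file does
#'   not carry them.
#' @return Long-format landmark data frame.
#' @export
read_landmarks <- function(path, dialect = c("long", "dlc"),
                           mapping = NULL, confidence_threshold = 0.6,
                           animal_id = "a01", condition = "baseline") {
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("frame_id", "landmark", "x", "y")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("malformed long landmark file, missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    key <- paste(df$frame_id, df$landmark, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- unique(key[duplicated(key)])[1]
      stop("duplicate (frame, landmark) pair: ", gsub("\r", "/", dup),
           call. = FALSE)
    }
    bad <- setdiff(unique(df$landmark), landmark_vocabulary())
    if (length(bad)) {
      stop("landmark name(s) outside canonical vocabulary: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if ("confidence" %in% names(df)) {
      df <- df[is.na(df$confidence) |
                 df$confidence >= confidence_threshold, , drop = FALSE]
    }
    for (col in c("excluded")) {
      if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
    }
    rownames(df) <- NULL
    return(df)
  }
  hdr <- utils::read.csv(path, header = FALSE, nrows = 3,
                         stringsAsFactors = FALSE)
  if (nrow(hdr) < 3L) stop("malformed pose-estimation header", call. = FALSE)
  bodyparts <- as.character(unlist(hdr[2, -1]))
  coords <- as.character(unlist(hdr[3, -1]))
  if (!all(coords %in% c("x", "y", "likelihood"))) {
    stop("malformed pose-estimation header: third row must be ",
         "x/y/likelihood", call. = FALSE)
  }
  dat <- utils::read.csv(path, header = FALSE, skip = 3,
                         stringsAsFactors = FALSE)
  if (is.null(mapping)) {
    mapping <- stats::setNames(landmark_vocabulary(), landmark_vocabulary())
  }
  unmapped <- setdiff(unique(bodyparts), names(mapping))
  if (length(unmapped)) {
    message("unmapped body part(s) skipped: ",
            paste(unmapped, collapse = ", "))
  }
  rows <- list()
  for (bp in intersect(unique(bodyparts), names(mapping))) {
    ix <- which(bodyparts == bp & coords == "x") + 1L
    iy <- which(bodyparts == bp & coords == "y") + 1L
    il <- which(bodyparts == bp & coords == "likelihood") + 1L
    conf <- if (length(il)) as.numeric(dat[[il[1]]]) else NA_real_
    rows[[bp]] <- data.frame(
      frame_id = sprintf("f%06d", seq_len(nrow(dat))),
      animal_id = animal_id, experiment_id = "import",
      condition = condition, phase_time_s = NA_real_,
      excluded = FALSE, exclusion_reason = "none", side = "right",
      landmark = mapping[[bp]],
      x = as.numeric(dat[[ix[1]]]), y = as.numeric(dat[[iy[1]]]),
      confidence = conf)
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$frame_id), , drop = FALSE]
  df <- df[is.na(df$confidence) |
             df$confidence >= confidence_threshold, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a long-format landmark table
#'
#' @param landmarks Long-format landmark data frame.
#' @param path Output CSV path.
#' @export
write_landmarks <- function(landmarks, path) {
  utils::write.csv(landmarks, path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' YAML file describing a run: input paths, body-part mapping, tasting
#' events and condition windows, statistical settings (alpha, number of
#' Bonferroni comparisons, post-hoc method), structure settings (parallel
#' analysis iterations, embedding hyperparameters), and seeds. Unknown
#' top-level keys are rejected so typos fail loudly.
#'
#' @param path YAML file.
#' @return Named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("inputs", "mapping", "tasting_events", "conditions",
             "alpha", "m", "posthoc", "confidence_threshold",
             "pca_scale", "parallel_iterations", "embedding", "seed",
             "output_dir", "baseline")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(alpha = 0.05, m = 1, posthoc = "tukey",
                   confidence_threshold = 0.6, pca_scale = TRUE,
                   parallel_iterations = 1000,
                   embedding = list(metric = "euclidean",
                                    n_neighbors = 15, min_dist = 0.1),
                   seed = 1, baseline = "baseline")
  out <- utils::modifyList(defaults, cfg)
  for (p in unlist(out$inputs)) {
    if (!file.exists(p)) stop("input path does not exist: ", p,
                              call. = FALSE)
  }
  out
}

#' Write a JSON run manifest
#'
#' Every pipeline run records what produced its outputs: package version,
#' seeds, settings, and the SHA-like content fingerprints of the inputs,
#' so any artifact can be regenerated from its manifest.
#'
#' @param path Output JSON path.
#' @param stage Stage label (e.g. `"simulate"`, `"profile"`).
#' @param settings Named list of settings to echo.
#' @param inputs Character vector of input file paths (fingerprinted).
#' @param seed Integer seed used by the stage (if any).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, stage, settings = list(),
                           inputs = character(), seed = NULL) {
  fingerprint <- vapply(inputs, function(p) {
    if (!file.exists(p)) return(NA_character_)
    # cheap stable content fingerprint: size + sum of byte values
    bytes <- readBin(p, "raw", file.info(p)$size)
    sprintf("%d-%.0f", length(bytes), sum(as.integer(bytes)))
  }, character(1))
  manifest <- list(
    package = "facemetrics",
    version = as.character(utils::packageVersion("facemetrics")),
    stage = stage,
    seed = seed,
    settings = settings,
    inputs = as.list(fingerprint))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
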