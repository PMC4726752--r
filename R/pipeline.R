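#' Validate a run configuration
#'
#' Checks an analysis configuration and reports every problem at once,
#' not just the first.
#'
#' @param config A named list (or path to a JSON document): fields
#'   `ensemble` (path or ensemble tibble), `reference` (path or frame),
#'   `site_atoms` (character vector of atom specs), optional `mapping`
#'   (named character vector of spec replacements), `choke_pairs` (list
#'   of 2-vectors of residue ids), optional `salt_bridge_pairs` (list of
#'   `c(basic, acidic)` residue ids), `threshold` (default 4),
#'   `min_diameter` (default = threshold), `select_n` (default 5),
#'   optional `out_dir`, optional `seed`.
#' @return The validated config (paths loaded into tibbles), invisibly
#'   usable by [run_analysis()].
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (!is.null(config$mapping)) config$mapping <- unlist(config$mapping)
    if (!is.null(config$choke_pairs) && !is.list(config$choke_pairs)) {
      config$choke_pairs <- apply(config$choke_pairs, 1, c,
                                  simplify = FALSE)
    }
  }
  problems <- character()
  note <- function(...) problems <<- c(problems, paste0(...))

  for (field in c("ensemble", "reference")) {
    v <- config[[field]]
    if (is.null(v)) {
      note("missing field '", field, "'")
    } else if (is.character(v)) {
      if (!file.exists(v)) note(field, " file not found: ", v)
    } else if (!is.data.frame(v)) {
      note(field, " must be a path or an ensemble tibble")
    }
  }
  if (is.null(config$site_atoms) || length(config$site_atoms) < 2) {
    note("site_atoms must list at least 2 atom specs")
  }
  if (is.null(config$choke_pairs) || length(config$choke_pairs) == 0) {
    note("choke_pairs must list at least one residue pair")
  } else if (any(vapply(config$choke_pairs, length, 0L) != 2)) {
    note("each choke pair must have exactly 2 residue ids")
  }
  config$threshold <- config$threshold %||% 4
  config$min_diameter <- config$min_diameter %||% config$threshold
  config$select_n <- config$select_n %||% 5
  if (config$threshold < 0) note("threshold must be >= 0")
  if (config$select_n < 1) note("select_n must be >= 1")

  if (length(problems) > 0) {
    stop("invalid configuration (", length(problems), " problem(s)):\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  if (is.character(config$ensemble)) {
    config$ensemble_path <- config$ensemble
    config$ensemble <- read_structure(config$ensemble)
  }
  if (is.character(config$reference)) {
    config$reference_path <- config$reference
    config$reference <- read_structure(config$reference)
  }
  config
}

echo_config <- function(config) {
  keep <- setdiff(names(config), c("ensemble", "reference"))
  cfg <- config[keep]
  cfg$ensemble <- config$ensemble_path %||% "<in-memory ensemble>"
  cfg$reference <- config$reference_path %||% "<in-memory frame>"
  cfg
}

#' Run the full conformational-analysis workflow
#'
#' Orchestrates the pipeline on a structure ensemble: score every frame
#' against the reference active-site descriptor, track choke-point
#' diameters for each configured residue pair, classify the channel as
#' open/closed/blocked, detect salt bridges if configured, and select
#' catalytically plausible frames (open channel, lowest score) for
#' docking. A failure in one choke pair does not abort the others; such
#' partial results are flagged in the report.
#'
#' @param config See [validate_config()].
#' @return An object of class `cp_run_report`: list with `frames` (one
#'   row per frame: score, per-pair diameters, open flags, salt-bridge
#'   flags), `selection`, `classification` (per pair), `failed_pairs`,
#'   `config` (effective configuration echo) and `elapsed_s`.
#' @export
run_analysis <- function(config) {
  t0 <- proc.time()["elapsed"]
  config <- validate_config(config)
  ens <- config$ensemble
  ref <- config$reference

  message("stage 1/4: scoring ", n_frames(ens), " frame(s)")
  descriptor <- build_descriptor(ref, config$site_atoms,
                                 reference_id = config$reference_path %||%
                                   "reference")
  scores <- score_frames(descriptor, ens, mapping = config$mapping)
  frames_tbl <- tibble::as_tibble(scores)[, c("frame", "S")]

  message("stage 2/4: choke-point diameters (",
          length(config$choke_pairs), " pair(s))")
  classification <- list()
  failed <- character()
  first_series <- NULL
  for (pair in config$choke_pairs) {
    label <- paste(pair, collapse = "_")
    res <- tryCatch(diameter_series(ens, pair[1], pair[2]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("choke pair ", label, " failed: ", conditionMessage(res),
              " (partial results)", call. = FALSE)
      failed <- c(failed, label)
      next
    }
    if (is.null(first_series)) first_series <- res
    state <- classify_channel(res, threshold = config$threshold)
    classification[[label]] <- glance(state)
    frames_tbl[[paste0("diameter_", label)]] <- res$diameter
    frames_tbl[[paste0("open_", label)]] <- state$open
  }
  if (is.null(first_series)) {
    stop("all choke pairs failed; nothing to classify", call. = FALSE)
  }

  message("stage 3/4: salt bridges")
  bridges <- list()
  for (pair in config$salt_bridge_pairs %||% list()) {
    label <- paste(pair, collapse = "_")
    res <- tryCatch(salt_bridge_series(ens, pair[1], pair[2]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("salt-bridge pair ", label, " failed: ",
              conditionMessage(res), call. = FALSE)
      failed <- c(failed, paste0("salt_bridge_", label))
      next
    }
    bridges[[label]] <- glance(res)
    frames_tbl[[paste0("bridged_", label)]] <- res$bridged
  }

  message("stage 4/4: frame selection")
  selection <- withCallingHandlers(
    select_frames(scores, first_series,
                  min_diameter = config$min_diameter, n = config$select_n),
    warning = function(w) {
      message("selection: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  report <- structure(list(
    frames = frames_tbl,
    selection = selection,
    classification = dplyr::bind_rows(classification, .id = "pair"),
    salt_bridges = if (length(bridges) > 0) {
      dplyr::bind_rows(bridges, .id = "pair")
    } else NULL,
    failed_pairs = failed,
    descriptor = descriptor,
    config = echo_config(config),
    version = as.character(utils::packageVersion("chokepoint")),
    elapsed_s = unname(proc.time()["elapsed"] - t0)),
    class = "cp_run_report")

  if (!is.null(config$out_dir)) write_report(report, config, ens)
  report
}

write_report <- function(report, config, ens) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(config$out_dir, "frames.tsv")
  utils::write.table(report$frames, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary <- list(config = report$config,
                  classification = report$classification,
                  selection = report$selection,
                  failed_pairs = report$failed_pairs,
                  version = report$version)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (nrow(report$selection) > 0) {
    sel <- ens[ens$frame %in% report$selection$frame, , drop = FALSE]
    # renumber selected frames consecutively for a standalone PDB
    sel$frame <- match(sel$frame, sort(unique(sel$frame))) - 1L
    write_structure(as_ensemble(sel),
                    file.path(config$out_dir, "selected_frames.pdb"))
  }
  invisible(config$out_dir)
}

#' @export
print.cp_run_report <- function(x, ...) {
  cat("<chokepoint run report>\n")
  cat("  frames analysed:", nrow(x$frames), "\n")
  if (nrow(x$classification) > 0) {
    for (i in seq_len(nrow(x$classification))) {
      r <- x$classification[i, ]
      cat(sprintf("  pair %s: open fraction %.2f%s\n", r$pair,
                  r$open_fraction,
                  if (r$blocked_persistently) " (persistently blocked)"
                  else ""))
    }
  }
  cat("  frames selected:", nrow(x$selection), "\n")
  if (length(x$failed_pairs) > 0) {
    cat("  failed stages:", paste(x$failed_pairs, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
glance.cp_run_report <- function(x, ...) {
  tibble::tibble(n_frames = nrow(x$frames),
                 n_selected = nrow(x$selection),
                 n_pairs = nrow(x$classification),
                 n_failed = length(x$failed_pairs),
                 elapsed_s = x$elapsed_s)
}
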