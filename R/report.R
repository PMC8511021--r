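# Plain-text reporting and run manifests.
#
# The package's functions are its command surface; this module renders
# their results into a single markdown summary mirroring the structure
# of a randomness-fingerprint analysis (identification AUC by pattern
# length, classical RNGT indices, individuality bands), and records a
# run manifest so that identical inputs reproduce identical outputs.

#' Write a run manifest
#'
#' Records the master seed, package version, input digests and an
#' arbitrary parameter list as JSON next to the analysis outputs.  Two
#' runs with identical manifest inputs produce identical outputs
#' (timestamps excepted).
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed of the run.
#' @param inputs Named character vector of input file paths (digested
#'   with md5).
#' @param params Optional named list of parameters to record.
#' @return The manifest path, invisibly.
#' @export
run_manifest <- function(dir, seed, inputs = character(0), params = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  digests <- if (length(inputs)) {
    vapply(inputs, function(f) unname(tools::md5sum(f)), character(1))
  } else character(0)
  manifest <- list(
    package = "rngprint",
    version = as.character(utils::packageVersion("rngprint")),
    seed = seed,
    inputs = as.list(digests),
    params = params,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

fmt_tbl <- function(df, digits = 4) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  header <- paste(names(df), collapse = " | ")
  sep <- paste(rep("---", ncol(df)), collapse = " | ")
  body <- apply(df, 1L, function(r) paste(trimws(r), collapse = " | "))
  c(paste("|", header, "|"), paste("|", sep, "|"),
    paste("|", body, "|"))
}

#' Render a markdown summary of analysis results
#'
#' @param path Output file path (markdown).
#' @param identification Optional `identification_result` (or a named
#'   list of them, e.g. DLS and exact baselines).
#' @param rngt Optional `rngt_summary`.
#' @param individuality Optional `individuality_curve`.
#' @param bands Optional band report from [band_top_patterns()].
#' @param familiar Optional tibble from [familiar_pattern_test()].
#' @return `path`, invisibly.  Missing sections are flagged in the
#'   document rather than silently dropped.
#' @export
write_report <- function(path, identification = NULL, rngt = NULL,
                         individuality = NULL, bands = NULL,
                         familiar = NULL) {
  lines <- c("# Random-generation fingerprint report", "")
  lines <- c(lines, "## Identification performance", "")
  if (!is.null(identification)) {
    idl <- if (inherits(identification, "identification_result"))
      list(result = identification) else identification
    for (nm in names(idl)) {
      r <- idl[[nm]]
      lines <- c(lines,
                 sprintf("### %s (scheme %s, scoring %s)", nm, r$scheme,
                         r$scoring), "",
                 fmt_tbl(r$summary), "")
    }
  } else {
    lines <- c(lines, "_identification results missing_", "")
  }
  lines <- c(lines, "## RNGT indices", "")
  if (!is.null(rngt)) {
    lines <- c(lines, fmt_tbl(rngt$session_summary), "")
    if (!is.null(rngt$paired)) {
      lines <- c(lines, "Paired session test:", "", fmt_tbl(rngt$paired), "")
    }
  } else {
    lines <- c(lines, "_RNGT results missing_", "")
  }
  lines <- c(lines, "## Individuality", "")
  if (!is.null(individuality)) {
    ex <- individuality[c(1L, which.max(individuality$delta),
                          nrow(individuality)), ]
    lines <- c(lines, "Delta (between - within) at curve landmarks:", "",
               fmt_tbl(ex), "")
  } else {
    lines <- c(lines, "_individuality curve missing_", "")
  }
  if (!is.null(bands)) {
    lines <- c(lines, "Top patterns per band:", "", fmt_tbl(bands), "")
  }
  if (!is.null(familiar)) {
    lines <- c(lines, "Familiar-pattern tests:", "", fmt_tbl(familiar), "")
  }
  writeLines(lines, path)
  invisible(path)
}
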