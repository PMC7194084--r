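#' svintegrate: multi-caller structural variant integration
#'
#' Parse, filter, merge, annotate and visualize structural-variant (SV)
#' predictions from up to seven short-read SV callers.  Two predictions of
#' the same SV type are considered concordant when their reciprocal
#' coordinate overlap exceeds a threshold (default 80%); concordant
#' predictions are clustered by single linkage and clusters supported by at
#' least `min_methods` distinct callers are merged into unified SVs whose
#' breakpoints are the means of the member breakpoints.
#'
#' @keywords internal
#' @aliases svintegrate-package
"_PACKAGE"

# Canonical SV types handled throughout the package.  Coordinates are
# 1-based inclusive everywhere outside the format readers/writers.
SV_TYPES <- c("del", "dup", "inv")

SUPPORTED_CALLERS <- c("breakdancer", "pindel", "cnvnator", "delly",
                       "svseq", "lumpy", "softsearch")

# SV types each caller can predict.
CALLER_TYPES <- list(
  breakdancer = c("del", "inv"),
  pindel      = c("del", "dup", "inv"),
  cnvnator    = c("del", "dup"),
  delly       = c("del", "dup", "inv"),
  svseq       = "del",
  lumpy       = c("del", "dup", "inv"),
  softsearch  = c("del", "dup", "inv")
)

# Display names used in merged `methods` strings.
CALLER_LABELS <- c(breakdancer = "BreakDancer", pindel = "Pindel",
                   cnvnator = "CNVnator", delly = "Delly",
                   svseq = "SVseq2", lumpy = "Lumpy",
                   softsearch = "SoftSearch")

#' Merge and filter parameters
#'
#' Container for every tunable threshold of the pipeline: the reciprocal
#' overlap fraction required to link two predictions, the minimum number of
#' distinct supporting callers for a merged SV, the global size window, and
#' the per-caller support gates.
#'
#' @param overlap_frac Reciprocal overlap threshold; two same-type
#'   predictions are linked when their reciprocal overlap is strictly
#'   greater than this fraction.  Default 0.8.
#' @param min_methods Minimum number of distinct callers supporting a
#'   cluster for it to be merged; clusters below this are discarded.
#'   Default 2.
#' @param min_size,max_size Global size window in bp; predictions whose
#'   effective size (see [effective_size()]) falls outside
#'   \[`min_size`, `max_size`\] are filtered by every reader.  Defaults 100
#'   and 1e7 (10 Mb).
#' @param per_caller Named list of per-caller gate overrides; unspecified
#'   gates keep their defaults (BreakDancer: `min_score = 60`,
#'   `min_pe = 3`; Pindel/SVseq2: `min_sr = 3`; DELLY: `min_support = 3`
#'   on PE+SR; Lumpy: `min_su = 3`; SoftSearch: `min_sr = 3` and
#'   `min_pe = 3`, both required; CNVnator: none — it is a read-depth
#'   caller).
#' @return An object of class `MergeParams` (a validated list).
#' @examples
#' p <- merge_params(overlap_frac = 0.9)
#' p$per_caller$breakdancer$min_score
#' @export
merge_params <- function(overlap_frac = 0.8, min_methods = 2,
                         min_size = 100, max_size = 1e7,
                         per_caller = list()) {
  defaults <- list(
    breakdancer = list(min_score = 60, min_pe = 3),
    pindel      = list(min_sr = 3),
    cnvnator    = list(),
    delly       = list(min_support = 3),
    svseq       = list(min_sr = 3),
    lumpy       = list(min_su = 3),
    softsearch  = list(min_sr = 3, min_pe = 3)
  )
  if (length(per_caller)) {
    bad <- setdiff(names(per_caller), SUPPORTED_CALLERS)
    if (length(bad))
      stop_config("unknown caller in per_caller overrides: ",
                  paste(bad, collapse = ", "))
    for (cl in names(per_caller))
      defaults[[cl]][names(per_caller[[cl]])] <- per_caller[[cl]]
  }
  p <- structure(list(overlap_frac = as.numeric(overlap_frac),
                      min_methods = as.integer(min_methods),
                      min_size = as.numeric(min_size),
                      max_size = as.numeric(max_size),
                      per_caller = defaults),
                 class = "MergeParams")
  validate_merge_params(p)
  p
}

validate_merge_params <- function(p) {
  stopifnot(inherits(p, "MergeParams"))
  if (!(p$overlap_frac > 0 && p$overlap_frac <= 1))
    stop_config("overlap_frac must be in (0, 1]")
  if (p$min_methods < 1L)
    stop_config("min_methods must be >= 1")
  if (!(p$min_size > 0 && p$min_size < p$max_size))
    stop_config("need 0 < min_size < max_size")
  invisible(p)
}

#' Read pipeline parameters from a key=value config file
#'
#' Plain-text config: one `key = value` pair per line, `#` comments.
#' Global keys are `overlap_frac`, `min_methods`, `min_size`, `max_size`,
#' `window`; per-caller gates use dotted keys, e.g.
#' `breakdancer.min_score = 70`.
#'
#' @param path Path to the config file.
#' @return A `MergeParams` object; a `window` key, if present, is attached
#'   as attribute `"window"`.
#' @export
read_merge_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*[=:]\\s*(.+)$", lines))
  bad <- lines[vapply(kv, length, 1L) != 3L]
  if (length(bad))
    stop_config("unparsable config line(s): ", paste(bad, collapse = "; "))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- as.numeric(vapply(kv, `[`, "", 3L))
  if (anyNA(vals)) stop_config("non-numeric config value")
  global <- list(); per <- list()
  for (i in seq_along(keys)) {
    if (grepl(".", keys[i], fixed = TRUE)) {
      parts <- strsplit(keys[i], ".", fixed = TRUE)[[1L]]
      per[[parts[1L]]][[parts[2L]]] <- vals[i]
    } else {
      global[[keys[i]]] <- vals[i]
    }
  }
  window <- global$window
  global$window <- NULL
  args <- global[intersect(names(global),
                           c("overlap_frac", "min_methods",
                             "min_size", "max_size"))]
  unknown <- setdiff(names(global), names(args))
  if (length(unknown))
    stop_config("unknown config key(s): ", paste(unknown, collapse = ", "))
  p <- do.call(merge_params, c(args, list(per_caller = per)))
  if (!is.null(window)) attr(p, "window") <- window
  p
}

#' Span of a 1-based inclusive interval
#'
#' @param pos1,pos2 Start and end coordinates (1-based, inclusive).
#' @return `pos2 - pos1 + 1`; a single base has span 1.  Vectorized.
#' @export
span <- function(pos1, pos2) {
  stopifnot(all(pos1 <= pos2))
  pos2 - pos1 + 1
}

#' Effective SV size used by the global size filter
#'
#' Callers may report a signed size that differs from the coordinate span
#' (an inversion can be printed with breakpoints 47 bp apart and size
#' -105).  The size filter therefore tests `|size|` when a size was
#' reported and falls back to the coordinate span otherwise.
#'
#' @param size Caller-reported size (may be negative or `NA`).
#' @param pos1,pos2 Breakpoints, used when `size` is `NA`.
#' @return Effective size in bp.  Vectorized.
#' @export
effective_size <- function(size, pos1, pos2) {
  out <- abs(size)
  miss <- is.na(out)
  if (any(miss)) out[miss] <- span(pos1[miss], pos2[miss])
  out
}

#' Reciprocal overlap of two intervals
#'
#' `min(o / len(a), o / len(b))` where `o` is the length of the
#' intersection (0 when disjoint) and lengths are 1-based inclusive spans.
#' Chromosome equality is the caller's responsibility.
#'
#' @param start1,end1 First interval.
#' @param start2,end2 Second interval.
#' @return Fraction in \[0, 1\].  Vectorized over all four arguments.
#' @examples
#' reciprocal_overlap(100, 199, 150, 249)  # 0.5
#' @export
reciprocal_overlap <- function(start1, end1, start2, end2) {
  o <- pmin(end1, end2) - pmax(start1, start2) + 1
  o <- pmax(o, 0)
  pmin(o / span(start1, end1), o / span(start2, end2))
}

#' Normalize a caller's SV-type label to del/dup/inv
#'
#' @param label Type label as printed by the caller (e.g. `"DEL"`, `"TD"`,
#'   `"deletion"`).
#' @param method Caller name, for error context only.
#' @return One of `"del"`, `"dup"`, `"inv"`, or `NA_character_` for labels
#'   outside the supported SV universe (translocations etc.); readers log
#'   such records as skipped.  Vectorized over `label`.
#' @export
normalize_type <- function(label, method = "unknown") {
  map <- c(DEL = "del", D = "del", DELETION = "del",
           DUP = "dup", TD = "dup", DUPLICATION = "dup",
           "DUP:TANDEM" = "dup",
           INV = "inv", INVERSION = "inv")
  canon <- c(del = "del", dup = "dup", inv = "inv")
  up <- toupper(label)
  out <- unname(ifelse(up %in% names(map), map[up], canon[tolower(label)]))
  unname(out)
}

# round half away from zero; base round() is banker's rounding and merged
# breakpoints must be stable integers (mean of 100 and 111 -> 106).
round_half_up <- function(x) floor(x + 0.5)

# ---- condition helpers -------------------------------------------------
# config errors exit the CLI with status 2, data errors with status 1.
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("sv_config_error", "error")))
}
stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("sv_data_error", "error")))
}

# ---- record/callset containers ----------------------------------------

# canonical empty record table
empty_records <- function() {
  data.frame(chromosome = character(), pos1 = integer(), pos2 = integer(),
             size = numeric(), info = character(),
             stringsAsFactors = FALSE)
}

sort_records <- function(df) {
  df <- df[order(df$chromosome, df$pos1, df$pos2), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Construct a per-caller call set
#'
#' A `CallSet` mirrors the per-type list structure the field is used to:
#' one data frame per SV type (`del`, `dup`, `inv`) with columns
#' `chromosome`, `pos1`, `pos2`, `size`, `info`, plus a `method` attribute
#' carrying the caller's display name.
#'
#' @param method Caller key (one of `breakdancer`, `pindel`, `cnvnator`,
#'   `delly`, `svseq`, `lumpy`, `softsearch`) or a free display name.
#' @param records Named list mapping sv_type to record data frames.
#' @param report Optional [ReaderReport] attached as attribute.
#' @return A `CallSet` object.
#' @export
callset <- function(method, records = list(), report = NULL) {
  label <- if (method %in% names(CALLER_LABELS)) CALLER_LABELS[[method]]
           else method
  types <- if (method %in% names(CALLER_TYPES)) CALLER_TYPES[[method]]
           else intersect(SV_TYPES, names(records))
  out <- lapply(types, function(tp) {
    df <- records[[tp]]
    if (is.null(df)) return(empty_records())
    df <- df[, c("chromosome", "pos1", "pos2", "size", "info")]
    stopifnot(all(df$pos1 <= df$pos2))
    sort_records(df)
  })
  names(out) <- types
  structure(out, method = label, caller = method, report = report,
            class = "CallSet")
}

#' @export
print.CallSet <- function(x, ...) {
  cat("CallSet:", attr(x, "method"), "\n")
  for (tp in names(x))
    cat(sprintf("  %s: %d records\n", tp, nrow(x[[tp]])))
  invisible(x)
}

#' Retrieve the reader report attached to a CallSet
#'
#' @param x A `CallSet` returned by one of the `read_*` functions.
#' @return The `ReaderReport`: a list with `method`, `raw_count` and
#'   `kept_count` (named integer vectors per sv_type) and `skipped`, a data
#'   frame with columns `file`, `line`, `sv_type`, `reason`.
#' @export
reader_report <- function(x) attr(x, "report")

#' @export
print.ReaderReport <- function(x, ...) {
  cat("ReaderReport:", x$method, "\n")
  for (tp in names(x$raw_count))
    cat(sprintf("  %s: raw %d, kept %d\n", tp,
                x$raw_count[[tp]], x$kept_count[[tp]]))
  if (nrow(x$skipped)) {
    tab <- table(x$skipped$reason)
    for (r in names(tab)) cat(sprintf("  skipped [%s]: %d\n", r, tab[[r]]))
  }
  invisible(x)
}

# parse "k1=v1;k2=v2" info strings into a named character vector
parse_info <- function(info) {
  if (!nzchar(info)) return(character())
  parts <- strsplit(info, ";", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(x) x[2L], ""),
                  vapply(kv, function(x) x[1L], ""))
}

# numeric value of one key of an info string (NA when absent); vectorized
info_field <- function(info, key) {
  m <- regmatches(info,
                  regexec(paste0("(?:^|;|:)", key, "=([-0-9.eE+]+)"), info))
  vapply(m, function(x) if (length(x) == 2L) as.numeric(x[2L]) else NA_real_,
         numeric(1))
}

# primary support value used to rank records of one caller:
# PE (BreakDancer), SR (Pindel/SVseq2), SU (Lumpy), PE+SR (DELLY),
# min(nSC, nRP) (SoftSearch; both gates must hold).  CNVnator has no
# read-support notion -> 0, ties broken by coordinates downstream.
support_score <- function(info, caller) {
  na0 <- function(x) ifelse(is.na(x), 0, x)
  switch(caller,
    breakdancer = na0(info_field(info, "PE")),
    pindel      = na0(info_field(info, "SR")),
    svseq       = na0(info_field(info, "SR")),
    lumpy       = na0(info_field(info, "SU")),
    delly       = na0(info_field(info, "PE")) + na0(info_field(info, "SR")),
    softsearch  = pmin(na0(info_field(info, "nSC")),
                       na0(info_field(info, "nRP"))),
    cnvnator    = rep(0, length(info)),
    # unknown caller: best effort over the common keys
    na0(info_field(info, "PE")) + na0(info_field(info, "SR")) +
      na0(info_field(info, "SU"))
  )
}

#' Read a chromosome-sizes file
#'
#' @param path Two-column TSV (`chrom`, `length_bp`), no header.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop_data("chromosome sizes file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  if (any(df$length <= 0)) stop_data("non-positive chromosome length")
  stats::setNames(df$length, df$chrom)
}
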