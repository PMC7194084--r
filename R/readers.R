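# Readers for the native output dialects of the seven supported SV
# callers.  Every reader: (1) parses its dialect into records with 1-based
# inclusive coordinates, (2) logs unparseable / out-of-universe records as
# skipped, (3) applies the caller's support gates and the global size
# window, and (4) returns a CallSet with a ReaderReport attached.
# Coordinate conventions converted on ingest are noted per reader.

# ---- shared machinery --------------------------------------------------

# gate list per caller: named list of predicate(df) -> logical (TRUE =
# violates).  Order matters: the first violated gate is the recorded
# reason.  The size window is always tested last.
caller_gates <- function(caller, params) {
  pc <- params$per_caller[[caller]]
  g <- list()
  if (caller == "breakdancer") {
    g[["score below threshold"]] <- function(df) df$score < pc$min_score
    g[["insufficient read-pair support"]] <- function(df) df$pe < pc$min_pe
  } else if (caller %in% c("pindel", "svseq")) {
    g[["insufficient split-read support"]] <- function(df) df$sr < pc$min_sr
  } else if (caller == "delly") {
    g[["insufficient read support"]] <-
      function(df) (df$pe + df$sr) < pc$min_support
  } else if (caller == "lumpy") {
    g[["insufficient read support"]] <- function(df) df$su < pc$min_su
  } else if (caller == "softsearch") {
    g[["insufficient split-read support"]] <- function(df) df$nsc < pc$min_sr
    g[["insufficient read-pair support"]] <- function(df) df$nrp < pc$min_pe
  }
  g[["size outside window"]] <- function(df) {
    es <- effective_size(df$size, df$pos1, df$pos2)
    es < params$min_size | es > params$max_size
  }
  g
}

empty_skips <- function() {
  data.frame(file = character(), line = integer(), sv_type = character(),
             reason = character(), stringsAsFactors = FALSE)
}

skip_rows <- function(file, line, sv_type, reason) {
  if (!length(line)) return(empty_skips())
  data.frame(file = file, line = as.integer(line), sv_type = sv_type,
             reason = reason, stringsAsFactors = FALSE)
}

# assemble a CallSet + ReaderReport from parsed raw records.  `raw` needs
# columns chromosome, pos1, pos2, size, info, sv_type, file, line plus the
# support columns its caller's gates read.  `parse_skips` accounts for
# records dropped before gating (unknown type, interchromosomal, ...).
build_callset <- function(caller, raw, parse_skips, params,
                          keep_all = FALSE) {
  types <- CALLER_TYPES[[caller]]
  raw_count <- vapply(types, function(tp) sum(raw$sv_type == tp), 1L)
  if (keep_all) {
    reasons <- rep(NA_character_, nrow(raw))
  } else {
    gates <- caller_gates(caller, params)
    reasons <- rep(NA_character_, nrow(raw))
    for (nm in names(gates)) {
      viol <- gates[[nm]](raw) & is.na(reasons)
      reasons[viol] <- nm
    }
  }
  kept <- raw[is.na(reasons), , drop = FALSE]
  dropped <- raw[!is.na(reasons), , drop = FALSE]
  skips <- rbind(parse_skips,
                 skip_rows(dropped$file, dropped$line, dropped$sv_type,
                           reasons[!is.na(reasons)]))
  kept_count <- vapply(types, function(tp) sum(kept$sv_type == tp), 1L)
  report <- structure(list(method = CALLER_LABELS[[caller]],
                           raw_count = raw_count, kept_count = kept_count,
                           skipped = skips),
                      class = "ReaderReport")
  recs <- split(kept[, c("chromosome", "pos1", "pos2", "size", "info")],
                factor(kept$sv_type, levels = types))
  callset(caller, recs, report = report)
}

num_or_stop <- function(x, what, file, line) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop_data(sprintf("%s: non-numeric %s at line %d: '%s'",
                      file, what, line[bad[1L]], x[bad[1L]]))
  out
}

# ---- BreakDancer -------------------------------------------------------

#' Read BreakDancer output
#'
#' BreakDancer writes all predictions to a single tab-delimited file
#' (`#`-prefixed header lines) with both breakpoints, the SV type, size,
#' a confidence score and the number of supporting discordant read pairs.
#' Coordinates are used as printed (1-based).  Deletions and inversions
#' are retained; other event types (insertions, translocations) and
#' interchromosomal rows are logged as skipped.
#'
#' Filters (defaults): score >= 60, supporting read pairs >= 3, effective
#' size within \[`min_size`, `max_size`\].
#'
#' @param path BreakDancer output file.
#' @param params A [merge_params()] object.
#' @param keep_all If `TRUE`, skip the quality gates and return every
#'   parsed in-universe record (used for round-trip auditing).
#' @return A `CallSet` (`del`, `inv`) with `info` strings
#'   `"score=S;PE=N"` and a [reader_report()] attached.
#' @export
read_breakdancer <- function(path, params = merge_params(),
                             keep_all = FALSE) {
  if (!file.exists(path)) stop_data("cannot read BreakDancer file: ", path)
  lines <- readLines(path, warn = FALSE)
  idx <- which(!startsWith(lines, "#") & nzchar(lines))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 10L))
    stop_data(sprintf("%s: expected >= 10 tab-delimited columns at line %d",
                      path, idx[which(nf < 10L)[1L]]))
  get <- function(i) vapply(fields, `[`, "", i)
  df <- data.frame(chromosome = get(1L),
                   pos1 = num_or_stop(get(2L), "Pos1", path, idx),
                   chrom2 = get(4L),
                   pos2 = num_or_stop(get(5L), "Pos2", path, idx),
                   type_raw = get(7L),
                   size = num_or_stop(get(8L), "Size", path, idx),
                   score = num_or_stop(get(9L), "Score", path, idx),
                   pe = num_or_stop(get(10L), "num_Reads", path, idx),
                   file = path, line = idx, stringsAsFactors = FALSE)
  df$sv_type <- normalize_type(df$type_raw, "breakdancer")
  inter <- df$chromosome != df$chrom2
  known <- !is.na(df$sv_type) &
    df$sv_type %in% CALLER_TYPES$breakdancer & !inter
  skips <- rbind(
    skip_rows(path, df$line[inter], NA_character_, "interchromosomal event"),
    skip_rows(path, df$line[!inter & !known], NA_character_,
              paste0("unsupported SV type '",
                     df$type_raw[!inter & !known], "'")))
  df <- df[known, , drop = FALSE]
  swap <- df$pos1 > df$pos2
  if (any(swap)) {
    tmp <- df$pos1[swap]; df$pos1[swap] <- df$pos2[swap]; df$pos2[swap] <- tmp
  }
  df$pos1 <- as.integer(df$pos1); df$pos2 <- as.integer(df$pos2)
  df$info <- sprintf("score=%s;PE=%s",
                     format(df$score, trim = TRUE, scientific = FALSE),
                     format(df$pe, trim = TRUE, scientific = FALSE))
  build_callset("breakdancer", df, skips, params, keep_all)
}

# ---- Pindel ------------------------------------------------------------

#' Read Pindel output
#'
#' Pindel writes one file per SV type (`*_D` deletions, `*_TD` tandem
#' duplications, `*_INV` inversions).  Each record is a multi-line block:
#' a `####...` separator, a summary header line, then the supporting
#' reads.  The header is tokenized and the fields after the `ChrID`, `BP`,
#' `Supports` and `S1` keywords are used.  Pindel's two `BP` positions
#' flank the event, so the record interval is `[BP1 + 1, BP2 - 1]`.
#'
#' Filters (defaults): supporting split reads >= 3, size window.
#' Malformed block headers are skipped and logged.
#'
#' @param paths A directory containing the per-type files, or an explicit
#'   character vector of files ending in `_D`, `_TD` or `_INV`.
#' @inheritParams read_breakdancer
#' @return A `CallSet` (`del`, `dup`, `inv`) with `info`
#'   `"SR=N;score=S"`.
#' @export
read_pindel <- function(paths, params = merge_params(), keep_all = FALSE) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "_(D|TD|INV)$", full.names = TRUE)
  if (!length(paths)) {
    warning("no Pindel output files found; returning empty CallSet")
    return(build_callset("pindel", cbind(empty_records(),
             data.frame(sv_type = character(), sr = numeric(),
                        file = character(), line = integer())),
             empty_skips(), params, keep_all))
  }
  rows <- list(); skips <- list()
  for (path in paths) {
    if (!file.exists(path)) stop_data("cannot read Pindel file: ", path)
    lines <- readLines(path, warn = FALSE)
    sep <- startsWith(lines, "######")
    hdr_idx <- which(sep) + 1L
    hdr_idx <- hdr_idx[hdr_idx <= length(lines)]
    for (i in hdr_idx) {
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
      chr_i <- match("ChrID", tok); bp_i <- match("BP", tok)
      sup_i <- match("Supports", tok); s1_i <- match("S1", tok)
      tp <- if (length(tok) >= 3L) normalize_type(tok[2L], "pindel")
            else NA_character_
      ok <- !is.na(chr_i) && !is.na(bp_i) && !is.na(sup_i) &&
        length(tok) >= max(chr_i + 1L, bp_i + 2L, sup_i + 1L) &&
        !is.na(tp)
      if (!ok) {
        skips[[length(skips) + 1L]] <-
          skip_rows(path, i, NA_character_, "malformed block header")
        next
      }
      bp1 <- suppressWarnings(as.numeric(tok[bp_i + 1L]))
      bp2 <- suppressWarnings(as.numeric(tok[bp_i + 2L]))
      sr <- suppressWarnings(as.numeric(tok[sup_i + 1L]))
      len <- suppressWarnings(as.numeric(tok[3L]))
      score <- if (!is.na(s1_i) && length(tok) >= s1_i + 1L)
        suppressWarnings(as.numeric(tok[s1_i + 1L])) else NA_real_
      if (anyNA(c(bp1, bp2, sr)) || bp2 - bp1 < 2) {
        skips[[length(skips) + 1L]] <-
          skip_rows(path, i, NA_character_, "malformed block header")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = tok[chr_i + 1L],
        pos1 = as.integer(bp1 + 1), pos2 = as.integer(bp2 - 1),
        size = if (is.na(len)) NA_real_ else len,
        sv_type = tp, sr = sr,
        info = sprintf("SR=%s;score=%s",
                       format(sr, trim = TRUE, scientific = FALSE),
                       if (is.na(score)) "NA"
                       else format(score, trim = TRUE, scientific = FALSE)),
        file = path, line = i, stringsAsFactors = FALSE)
    }
  }
  raw <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chromosome = character(), pos1 = integer(), pos2 = integer(),
               size = numeric(), sv_type = character(), sr = numeric(),
               info = character(), file = character(), line = integer(),
               stringsAsFactors = FALSE)
  skips <- if (length(skips)) do.call(rbind, skips) else empty_skips()
  build_callset("pindel", raw, skips, params, keep_all)
}

# ---- CNVnator ----------------------------------------------------------

#' Read CNVnator output
#'
#' CNVnator writes one call file per chromosome; the given directory must
#' contain only these final output files.  Each line holds the call type
#' (`deletion`/`duplication`), the region as `chrom:start-end`, the
#' caller's size estimate, the normalized read depth and four e-values.
#' The record size is recomputed as `end - start` (CNVnator bins make the
#' printed size one less than the inclusive span).  Any unparseable line
#' is a hard error naming the file, guarding against stray files.
#'
#' Filters: size window only — CNVnator is a read-depth caller with no
#' per-event read-support count.
#'
#' @param dir Directory of CNVnator call files.
#' @inheritParams read_breakdancer
#' @return A `CallSet` (`del`, `dup`) with `info`
#'   `"eval1=...;eval2=...;eval3=...;eval4=..."`.
#' @export
read_cnvnator <- function(dir, params = merge_params(), keep_all = FALSE) {
  if (!dir.exists(dir)) stop_data("not a directory: ", dir)
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  rows <- list()
  for (path in files) {
    lines <- readLines(path, warn = FALSE)
    lines_idx <- which(nzchar(trimws(lines)))
    if (!length(lines_idx)) next
    fields <- strsplit(trimws(lines[lines_idx]), "\\s+")
    nf <- vapply(fields, length, 1L)
    if (any(nf < 8L))
      stop_data(sprintf(
        "%s: not a CNVnator call file (line %d has %d fields)",
        path, lines_idx[which(nf < 8L)[1L]], min(nf)))
    get <- function(i) vapply(fields, `[`, "", i)
    tp <- normalize_type(get(1L), "cnvnator")
    reg <- regmatches(get(2L),
                      regexec("^([^:]+):([0-9]+)-([0-9]+)$", get(2L)))
    regok <- vapply(reg, length, 1L) == 4L
    if (any(is.na(tp)) || !all(regok))
      stop_data(sprintf("%s: not a CNVnator call file (line %d)",
                        path, lines_idx[which(is.na(tp) | !regok)[1L]]))
    pos1 <- as.integer(vapply(reg, `[`, "", 3L))
    pos2 <- as.integer(vapply(reg, `[`, "", 4L))
    ev <- lapply(5:8, function(i)
      num_or_stop(get(i), sprintf("e-value %d", i - 4L), path, lines_idx))
    rows[[length(rows) + 1L]] <- data.frame(
      chromosome = vapply(reg, `[`, "", 2L),
      pos1 = pmin(pos1, pos2), pos2 = pmax(pos1, pos2),
      size = as.numeric(pmax(pos1, pos2) - pmin(pos1, pos2)),
      sv_type = tp,
      info = sprintf("eval1=%s;eval2=%s;eval3=%s;eval4=%s",
                     format(ev[[1L]], trim = TRUE),
                     format(ev[[2L]], trim = TRUE),
                     format(ev[[3L]], trim = TRUE),
                     format(ev[[4L]], trim = TRUE)),
      file = path, line = lines_idx, stringsAsFactors = FALSE)
  }
  raw <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chromosome = character(), pos1 = integer(), pos2 = integer(),
               size = numeric(), sv_type = character(), info = character(),
               file = character(), line = integer(), stringsAsFactors = FALSE)
  build_callset("cnvnator", raw, empty_skips(), params, keep_all)
}

# ---- shared VCF extraction --------------------------------------------

# numeric INFO field; tolerates IntegerList-typed fields (summed) and
# absent keys (NA vector)
vcf_info_num <- function(inf, key, n) {
  if (!key %in% colnames(inf)) return(rep(NA_real_, n))
  v <- inf[[key]]
  if (methods::is(v, "List") || is.list(v))
    return(vapply(v, function(x) if (length(x)) sum(as.numeric(x))
                  else NA_real_, numeric(1)))
  as.numeric(v)
}

# parse an SV VCF (symbolic alleles, SVTYPE + END in INFO) into a raw
# record table.  VCF POS is the base preceding the event and END its last
# base, so pos1 = POS + 1, pos2 = END.
read_sv_vcf <- function(path, caller, support_keys) {
  if (!file.exists(path)) stop_data("cannot read VCF: ", path)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown")),
    error = function(e) stop_data(path, ": VCF parse failure: ",
                                  conditionMessage(e)))
  hdr <- rownames(VariantAnnotation::info(VariantAnnotation::header(vcf)))
  if (!all(c("SVTYPE", "END") %in% hdr))
    stop_data(path, ": VCF lacks SVTYPE/END INFO definitions")
  inf <- VariantAnnotation::info(vcf)
  n <- nrow(inf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  typ <- as.character(inf$SVTYPE)
  df <- data.frame(
    chromosome = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    end = vcf_info_num(inf, "END", n),
    type_raw = typ,
    file = path, line = seq_len(n), stringsAsFactors = FALSE)
  for (k in support_keys) df[[tolower(k)]] <- vcf_info_num(inf, k, n)
  df$sv_type <- normalize_type(df$type_raw, caller)
  df
}

finish_vcf_raw <- function(df, caller) {
  ok <- !is.na(df$sv_type) & df$sv_type %in% CALLER_TYPES[[caller]] &
    !is.na(df$end) & df$pos + 1 <= df$end
  skips <- skip_rows(df$file[!ok], df$line[!ok], NA_character_,
                     ifelse(is.na(df$sv_type[!ok]) |
                              !(df$sv_type[!ok] %in% CALLER_TYPES[[caller]]),
                            paste0("unsupported SV type '",
                                   df$type_raw[!ok], "'"),
                            "invalid coordinates"))
  df <- df[ok, , drop = FALSE]
  df$pos1 <- as.integer(df$pos + 1)
  df$pos2 <- as.integer(df$end)
  df$size <- NA_real_
  list(raw = df, skips = skips)
}

# ---- DELLY -------------------------------------------------------------

#' Read DELLY output
#'
#' DELLY reports SVs as VCF with symbolic alleles; `SVTYPE` and `END` are
#' required INFO keys and `PE` (discordant pairs) / `SR` (split reads) are
#' used as support.  The record interval is `[POS + 1, END]` (the VCF POS
#' of a symbolic allele is the base before the event).
#'
#' Filters (defaults): total support `PE + SR >= 3` (missing keys count as
#' 0), size window.
#'
#' @param paths One or more DELLY VCF files (DELLY historically writes one
#'   per SV type).
#' @inheritParams read_breakdancer
#' @return A `CallSet` (`del`, `dup`, `inv`) with `info` carrying the
#'   `PE=`/`SR=` values present in the file.
#' @export
read_delly <- function(paths, params = merge_params(), keep_all = FALSE) {
  raws <- list(); skips <- list()
  for (path in paths) {
    df <- read_sv_vcf(path, "delly", c("PE", "SR"))
    fin <- finish_vcf_raw(df, "delly")
    raws[[length(raws) + 1L]] <- fin$raw
    skips[[length(skips) + 1L]] <- fin$skips
  }
  raw <- do.call(rbind, raws)
  has_pe <- !is.na(raw$pe); has_sr <- !is.na(raw$sr)
  raw$info <- paste0(ifelse(has_pe, sprintf("PE=%g", raw$pe), ""),
                     ifelse(has_pe & has_sr, ";", ""),
                     ifelse(has_sr, sprintf("SR=%g", raw$sr), ""))
  raw$pe[!has_pe] <- 0; raw$sr[!has_sr] <- 0
  build_callset("delly", raw, do.call(rbind, skips), params, keep_all)
}

# ---- SVseq2 ------------------------------------------------------------

#' Read SVseq2 deletion output
#'
#' SVseq2 predicts deletions only.  The supported layout is a directory of
#' per-chromosome `*.del` files (chromosome name = file name without the
#' extension), one deletion per line: start, end, number of supporting
#' split reads (whitespace-separated).
#'
#' Filters (defaults): split reads >= 3, size window.
#'
#' @param dir_or_files Directory containing `*.del` files, or an explicit
#'   vector of such files.
#' @inheritParams read_breakdancer
#' @return A `CallSet` (`del` only) with `info` `"SR=N"`.
#' @export
read_svseq <- function(dir_or_files, params = merge_params(),
                       keep_all = FALSE) {
  paths <- dir_or_files
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.del$", full.names = TRUE)
  rows <- list()
  for (path in paths) {
    if (!file.exists(path)) stop_data("cannot read SVseq2 file: ", path)
    chrom <- sub("\\.del$", "", basename(path))
    lines <- readLines(path, warn = FALSE)
    idx <- which(nzchar(trimws(lines)))
    if (!length(idx)) next
    fields <- strsplit(trimws(lines[idx]), "\\s+")
    nf <- vapply(fields, length, 1L)
    if (any(nf < 3L))
      stop_data(sprintf("%s: expected 'start end split_reads' at line %d",
                        path, idx[which(nf < 3L)[1L]]))
    get <- function(i) vapply(fields, `[`, "", i)
    p1 <- num_or_stop(get(1L), "start", path, idx)
    p2 <- num_or_stop(get(2L), "end", path, idx)
    sr <- num_or_stop(get(3L), "split_reads", path, idx)
    rows[[length(rows) + 1L]] <- data.frame(
      chromosome = chrom, pos1 = as.integer(pmin(p1, p2)),
      pos2 = as.integer(pmax(p1, p2)), size = NA_real_,
      sv_type = "del", sr = sr,
      info = sprintf("SR=%s", format(sr, trim = TRUE, scientific = FALSE)),
      file = path, line = idx, stringsAsFactors = FALSE)
  }
  raw <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chromosome = character(), pos1 = integer(), pos2 = integer(),
               size = numeric(), sv_type = character(), sr = numeric(),
               info = character(), file = character(), line = integer(),
               stringsAsFactors = FALSE)
  build_callset("svseq", raw, empty_skips(), params, keep_all)
}

# ---- Lumpy -------------------------------------------------------------

#' Read Lumpy output
#'
#' Accepts either the Lumpy VCF (`SVTYPE`, `END`, and the `SU` total
#' evidence count in INFO) or the older BEDPE layout (breakpoint-pair
#' intervals; a `TYPE:` field names the event class and an `IDS:` field
#' lists per-evidence counts, which are summed into `SU`).  BEDPE is
#' 0-based half-open, so the event is `[start1 + 1, end2]`.
#'
#' Filters (defaults): `SU >= 3`, size window.
#'
#' @param path Lumpy VCF or BEDPE file.
#' @inheritParams read_breakdancer
#' @return A `CallSet` (`del`, `dup`, `inv`) with `info` `"SU=N"`.
#' @export
read_lumpy <- function(path, params = merge_params(), keep_all = FALSE) {
  if (!file.exists(path)) stop_data("cannot read Lumpy file: ", path)
  head1 <- readLines(path, n = 1L, warn = FALSE)
  if (length(head1) && startsWith(head1, "##fileformat=VCF")) {
    df <- read_sv_vcf(path, "lumpy", "SU")
    fin <- finish_vcf_raw(df, "lumpy")
    raw <- fin$raw; skips <- fin$skips
    raw$su[is.na(raw$su)] <- 0
  } else {
    lines <- readLines(path, warn = FALSE)
    idx <- which(!startsWith(lines, "#") & nzchar(lines))
    fields <- strsplit(lines[idx], "\t", fixed = TRUE)
    nf <- vapply(fields, length, 1L)
    if (any(nf < 11L))
      stop_data(sprintf("%s: expected >= 11 BEDPE columns at line %d",
                        path, idx[which(nf < 11L)[1L]]))
    get <- function(i) vapply(fields, `[`, "", i)
    tyf <- vapply(fields, function(f) {
      hit <- grep("^TYPE:", f, value = TRUE)
      if (length(hit)) sub("^TYPE:", "", hit[1L]) else NA_character_
    }, "")
    su <- vapply(fields, function(f) {
      hit <- grep("^IDS:", f, value = TRUE)
      if (!length(hit)) return(NA_real_)
      sum(as.numeric(unlist(regmatches(hit[1L],
                                       gregexpr("[0-9]+", hit[1L])))))
    }, numeric(1))
    df <- data.frame(chromosome = get(1L), chrom2 = get(4L),
                     pos1 = as.integer(num_or_stop(get(2L), "start1",
                                                   path, idx) + 1),
                     pos2 = as.integer(num_or_stop(get(6L), "end2",
                                                   path, idx)),
                     type_raw = tyf, su = su,
                     file = path, line = idx, stringsAsFactors = FALSE)
    df$sv_type <- normalize_type(df$type_raw, "lumpy")
    inter <- df$chromosome != df$chrom2
    ok <- !inter & !is.na(df$sv_type) & df$pos1 <= df$pos2
    skips <- rbind(
      skip_rows(path, df$line[inter], NA_character_,
                "interchromosomal event"),
      skip_rows(path, df$line[!inter & !ok], NA_character_,
                paste0("unsupported SV type '",
                       df$type_raw[!inter & !ok], "'")))
    raw <- df[ok, , drop = FALSE]
    raw$size <- NA_real_
    raw$su[is.na(raw$su)] <- 0
  }
  raw$info <- sprintf("SU=%g", raw$su)
  build_callset("lumpy", raw, skips, params, keep_all)
}

# ---- SoftSearch --------------------------------------------------------

#' Read SoftSearch output
#'
#' SoftSearch VCF with per-event soft-clipped read (`nSC`) and discordant
#' read-pair (`nRP`) counts in INFO, plus `SVTYPE` and `END`.
#'
#' Filters (defaults, conjunctive): `nSC >= 3` AND `nRP >= 3`, size
#' window.
#'
#' @param path SoftSearch VCF file.
#' @inheritParams read_breakdancer
#' @return A `CallSet` (`del`, `dup`, `inv`) with `info` `"nSC=a;nRP=b"`.
#' @export
read_softsearch <- function(path, params = merge_params(),
                            keep_all = FALSE) {
  df <- read_sv_vcf(path, "softsearch", c("nSC", "nRP"))
  fin <- finish_vcf_raw(df, "softsearch")
  raw <- fin$raw
  raw$nsc[is.na(raw$nsc)] <- 0; raw$nrp[is.na(raw$nrp)] <- 0
  raw$info <- sprintf("nSC=%g;nRP=%g", raw$nsc, raw$nrp)
  build_callset("softsearch", raw, fin$skips, params, keep_all)
}

# ---- within-caller overlap resolution ---------------------------------

#' Resolve overlapping predictions within a single caller
#'
#' Among same-type records of one caller whose reciprocal overlap chains
#' above `overlap_frac`, only the best-supported record is kept (largest
#' primary support value — PE, SR or SU as applicable to the caller — with
#' ties broken by smaller `pos1`, then smaller `pos2`).  Removed records
#' are appended to the attached report's skipped table.
#'
#' @param cs A `CallSet`.
#' @param params A [merge_params()] object.
#' @return The `CallSet` with self-overlaps resolved.
#' @export
resolve_self_overlaps <- function(cs, params = merge_params()) {
  stopifnot(inherits(cs, "CallSet"))
  caller <- attr(cs, "caller")
  report <- attr(cs, "report")
  out <- lapply(names(cs), function(tp) {
    df <- cs[[tp]]
    if (nrow(df) < 2L) return(df)
    cl <- cluster_svs(df, overlap_frac = params$overlap_frac)
    sup <- support_score(df$info, caller)
    keep <- unlist(lapply(split(seq_len(nrow(df)), cl), function(ix) {
      ord <- order(-sup[ix], df$pos1[ix], df$pos2[ix])
      ix[ord[1L]]
    }), use.names = FALSE)
    dropped <- setdiff(seq_len(nrow(df)), keep)
    if (length(dropped) && !is.null(report)) {
      report$skipped <<- rbind(report$skipped,
        skip_rows(NA_character_, dropped, tp,
                  "within-caller overlap resolved"))
      report$kept_count[[tp]] <<- report$kept_count[[tp]] - length(dropped)
    }
    sort_records(df[sort(keep), , drop = FALSE])
  })
  names(out) <- names(cs)
  structure(out, method = attr(cs, "method"), caller = caller,
            report = report, class = "CallSet")
}

#' Audit a CallSet against its caller's stated gates
#'
#' Independent post-hoc check used by the test-suite: re-parses each kept
#' record's `info` string and verifies every gate of [merge_params()] for
#' the CallSet's caller, plus the size window.
#'
#' @param cs A `CallSet`.
#' @param params A [merge_params()] object.
#' @return Invisibly `TRUE`; a gate violation raises an error describing
#'   the offending record.
#' @export
audit_callset <- function(cs, params = merge_params()) {
  caller <- attr(cs, "caller")
  pc <- params$per_caller[[caller]]
  for (tp in names(cs)) {
    df <- cs[[tp]]
    if (!nrow(df)) next
    es <- effective_size(df$size, df$pos1, df$pos2)
    bad <- es < params$min_size | es > params$max_size
    if (caller == "breakdancer")
      bad <- bad | info_field(df$info, "score") < pc$min_score |
        info_field(df$info, "PE") < pc$min_pe
    if (caller %in% c("pindel", "svseq"))
      bad <- bad | info_field(df$info, "SR") < pc$min_sr
    if (caller == "delly") {
      na0 <- function(x) ifelse(is.na(x), 0, x)
      bad <- bad | (na0(info_field(df$info, "PE")) +
                      na0(info_field(df$info, "SR"))) < pc$min_support
    }
    if (caller == "lumpy")
      bad <- bad | info_field(df$info, "SU") < pc$min_su
    if (caller == "softsearch")
      bad <- bad | info_field(df$info, "nSC") < pc$min_sr |
        info_field(df$info, "nRP") < pc$min_pe
    if (any(bad, na.rm = TRUE))
      stop_data(sprintf("audit failure: %s %s record %s:%d-%d (%s)",
                        caller, tp, df$chromosome[which(bad)[1L]],
                        df$pos1[which(bad)[1L]], df$pos2[which(bad)[1L]],
                        df$info[which(bad)[1L]]))
  }
  invisible(TRUE)
}

# dispatch table used by the CLI and pipeline helpers
caller_reader <- function(caller) {
  switch(caller,
         breakdancer = read_breakdancer, pindel = read_pindel,
         cnvnator = read_cnvnator, delly = read_delly,
         svseq = read_svseq, lumpy = read_lumpy,
         softsearch = read_softsearch,
         stop_config("unknown caller: ", caller))
}
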