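# Synthetic SV benchmark: plant non-overlapping ground-truth SVs on a
# toy genome, emit them in every supported caller dialect with boundary
# jitter, caller-unique false positives and deliberately sub-threshold
# records, then score merged output against the planted truth.  No reads
# are simulated — the fixtures model caller outputs, not sequencing.

#' Describe a simulated genome
#'
#' @param lengths Named numeric vector of chromosome lengths in bp.
#'   The default (5 chromosomes of 20 Mb) is comfortably larger than the
#'   footprint of the default truth set, so rejection-sampling placement
#'   converges quickly.
#' @return A `GenomeSpec` object.
#' @export
genome_spec <- function(lengths = stats::setNames(rep(2e7, 5),
                                                  sprintf("chr%02d", 1:5))) {
  if (any(lengths <= 0) || is.null(names(lengths)))
    stop_config("chromosome lengths must be positive and named")
  structure(list(chromosomes = lengths), class = "GenomeSpec")
}

# rejection-sampling placement over a shared occupancy registry; padded
# so that jittered copies of neighbours can never touch
place_interval <- function(occ, lens, size, pad, rng_tries = 200L) {
  for (i in seq_len(rng_tries)) {
    ch <- sample(names(lens), 1L, prob = lens)
    if (lens[[ch]] < size + 2) next
    p1 <- sample(seq(2L, as.integer(lens[[ch]] - size)), 1L)
    p2 <- p1 + size - 1L
    prev <- occ[[ch]]
    lo <- p1 - pad; hi <- p2 + pad
    if (!is.null(prev) && any(pmax(prev$s, lo) <= pmin(prev$e, hi))) next
    occ[[ch]] <- rbind(prev, data.frame(s = lo, e = hi))
    return(list(occ = occ, chromosome = ch, pos1 = p1, pos2 = p2))
  }
  NULL
}

#' Simulate ground-truth structural variants
#'
#' Truth SVs are placed uniformly over the genome (chromosomes weighted
#' by length) with log-uniform sizes, mutually non-overlapping with a
#' generous guard band so that jittered caller reports of distinct truth
#' SVs can never cluster together.  Deterministic under `seed`.
#'
#' @param spec A [genome_spec()].
#' @param n_per_type Named counts of truth SVs,
#'   default `c(del = 120, dup = 50, inv = 30)`.
#' @param size_range Size bounds in bp (log-uniform), default
#'   `c(200, 1e5)` — inside the pipeline's \[100 bp, 10 Mb\] window.
#' @param seed Integer seed; the global RNG state is left untouched.
#' @return Data frame with columns `id`, `chromosome`, `pos1`, `pos2`,
#'   `sv_type`, `size`.
#' @export
simulate_truth <- function(spec, n_per_type = c(del = 120, dup = 50,
                                                inv = 30),
                           size_range = c(200, 1e5), seed = 1L) {
  stopifnot(inherits(spec, "GenomeSpec"))
  if (size_range[1L] < 100 || size_range[1L] >= size_range[2L])
    stop_config("size_range must satisfy 100 <= lo < hi")
  lens <- spec$chromosomes
  withr::with_seed(seed, {
    rows <- list(); occ <- list()
    for (tp in intersect(SV_TYPES, names(n_per_type))) {
      n <- n_per_type[[tp]]
      if (n == 0) next
      for (i in seq_len(n)) {
        size <- round(exp(stats::runif(1, log(size_range[1L]),
                                       log(size_range[2L]))))
        pl <- place_interval(occ, lens, size,
                             pad = ceiling(0.3 * size) + 100L)
        if (is.null(pl))
          stop_data("cannot place truth SVs without overlap; ",
                    "genome too dense")
        occ <- pl$occ
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("truth_%s_%03d", tp, i), chromosome = pl$chromosome,
          pos1 = pl$pos1, pos2 = pl$pos2, sv_type = tp,
          size = pl$pos2 - pl$pos1 + 1L, stringsAsFactors = FALSE)
      }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(id = character(), chromosome = character(),
                 pos1 = integer(), pos2 = integer(), sv_type = character(),
                 size = integer(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

# supra-threshold support values per caller, as an info-ready list
sim_support <- function(caller, n) {
  switch(caller,
    breakdancer = data.frame(score = sample(60:99, n, TRUE),
                             pe = sample(3:30, n, TRUE)),
    pindel = data.frame(sr = sample(3:40, n, TRUE),
                        score = sample(10:60, n, TRUE)),
    cnvnator = data.frame(rd = round(stats::runif(n, 0, 3), 3),
                          e1 = signif(stats::runif(n, 1e-12, 1e-3), 6),
                          e2 = signif(stats::runif(n, 1e-12, 1e-3), 6),
                          e3 = signif(stats::runif(n, 1e-12, 1e-3), 6),
                          e4 = signif(stats::runif(n, 1e-12, 1e-3), 6)),
    delly = data.frame(pe = sample(3:30, n, TRUE),
                       sr = sample(0:10, n, TRUE)),
    svseq = data.frame(sr = sample(3:20, n, TRUE)),
    lumpy = data.frame(su = sample(3:40, n, TRUE)),
    softsearch = data.frame(nsc = sample(3:20, n, TRUE),
                            nrp = sample(3:20, n, TRUE)))
}

# sub-threshold variants of the support table: violate exactly the named
# filter, keep everything else passing
sim_violation <- function(caller, violation) {
  sup <- sim_support(caller, 1L)
  if (violation == "score") sup$score <- sample(0:59, 1L)
  if (violation == "support") {
    if (caller == "breakdancer") sup$pe <- sample(0:2, 1L)
    if (caller %in% c("pindel", "svseq")) sup$sr <- sample(0:2, 1L)
    if (caller == "delly") { sup$pe <- sample(0:2, 1L); sup$sr <- 0L }
    if (caller == "lumpy") sup$su <- sample(0:2, 1L)
    if (caller == "softsearch") sup$nsc <- sample(0:2, 1L)
  }
  sup
}

sub_violations <- function(caller, max_len) {
  v <- c("support", "size_small", "size_large")
  if (caller == "breakdancer") v <- c("score", v)
  if (caller == "cnvnator") v <- c("size_small", "size_large")
  if (max_len < 1.05e7) v <- setdiff(v, "size_large")
  v
}

#' Emit simulated caller output files in every requested dialect
#'
#' Each truth SV is reported by a random subset (>= 2) of the requested
#' callers able to predict its type, with both breakpoints independently
#' jittered by up to `jitter_frac` of the SV length — small enough
#' (`jitter_frac < (1 - overlap_frac) / 2`) that every jittered copy
#' keeps reciprocal overlap above threshold with its truth SV and with
#' its sibling reports.  Per caller, `fp_per_caller` caller-unique false
#' positives are planted away from everything else, and a
#' `sub_threshold_frac` share of additional records each violate exactly
#' one quality filter (score < 60, support < 3, size < 100 bp,
#' size > 10 Mb) to exercise the reader gates.
#'
#' @param truth Truth table from [simulate_truth()].
#' @param spec The [genome_spec()] the truth was simulated on.
#' @param callers Caller dialects to emit (default: five callers
#'   covering all three SV types).
#' @param jitter_frac Maximum boundary jitter as a fraction of SV length.
#' @param fp_per_caller Caller-unique false positives per caller.
#' @param sub_threshold_frac Share of deliberately filtered records per
#'   caller, relative to its true reports plus false positives.
#' @param out_dir Output directory (created).
#' @param seed Integer seed.
#' @param params [merge_params()]; used to validate `jitter_frac` and to
#'   bound false-positive sizes.
#' @return Invisibly, a list with the `manifest` and `calls` data frames
#'   and their file paths inside `out_dir`.  The manifest has one row per
#'   truth SV, false positive and sub-threshold record; `calls.tsv` lists
#'   every emitted caller record with its jittered coordinates and
#'   support string.
#' @export
emit_caller_outputs <- function(truth, spec,
                                callers = c("breakdancer", "pindel",
                                            "cnvnator", "delly", "lumpy"),
                                jitter_frac = 0.05, fp_per_caller = 0L,
                                sub_threshold_frac = 0,
                                out_dir, seed = 1L,
                                params = merge_params()) {
  bad <- setdiff(callers, SUPPORTED_CALLERS)
  if (length(bad))
    stop_config("unknown caller(s): ", paste(bad, collapse = ", "))
  if (jitter_frac >= (1 - params$overlap_frac) / 2)
    stop_config("jitter_frac must be < (1 - overlap_frac) / 2")
  stopifnot(inherits(spec, "GenomeSpec"))
  lens <- spec$chromosomes
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  withr::with_seed(seed, {
    calls <- list(); manifest <- list()

    # occupancy registry seeded with the (padded) truth footprint
    occ <- list()
    for (i in seq_len(nrow(truth))) {
      sz <- truth$size[i]; pad <- ceiling(0.3 * sz) + 100L
      occ[[truth$chromosome[i]]] <- rbind(occ[[truth$chromosome[i]]],
        data.frame(s = truth$pos1[i] - pad, e = truth$pos2[i] + pad))
    }

    # truth reports
    for (i in seq_len(nrow(truth))) {
      capable <- callers[vapply(callers, function(cl)
        truth$sv_type[i] %in% CALLER_TYPES[[cl]], TRUE)]
      if (length(capable) < 2L)
        stop_config("fewer than two requested callers support type ",
                    truth$sv_type[i])
      ks <- seq(2L, length(capable))     # sample() scalar trap: index it
      k <- ks[sample.int(length(ks), 1L)]
      rep_callers <- sample(capable, k)
      manifest[[length(manifest) + 1L]] <- data.frame(
        kind = "truth", id = truth$id[i],
        chromosome = truth$chromosome[i], pos1 = truth$pos1[i],
        pos2 = truth$pos2[i], sv_type = truth$sv_type[i],
        callers = paste(sort(rep_callers), collapse = ","),
        violation = "", stringsAsFactors = FALSE)
      sz <- truth$size[i]
      j <- floor(jitter_frac * sz)
      for (cl in rep_callers) {
        d <- if (j > 0) sample(seq(-j, j), 2L, TRUE) else c(0L, 0L)
        p1 <- max(2L, truth$pos1[i] + d[1L])
        p2 <- min(as.integer(lens[[truth$chromosome[i]]] - 1L),
                  truth$pos2[i] + d[2L])
        calls[[length(calls) + 1L]] <- cbind(
          data.frame(caller = cl, kind = "truth", truth_id = truth$id[i],
                     chromosome = truth$chromosome[i], pos1 = p1, pos2 = p2,
                     sv_type = truth$sv_type[i], violation = "",
                     stringsAsFactors = FALSE),
          sim_support(cl, 1L))
      }
    }

    # caller-unique false positives, away from everything else
    size_rng <- c(max(200, params$min_size * 2), 2e4)
    for (cl in callers) {
      for (i in seq_len(fp_per_caller)) {
        tp <- sample(CALLER_TYPES[[cl]], 1L)
        sz <- round(exp(stats::runif(1, log(size_rng[1L]),
                                     log(size_rng[2L]))))
        pl <- place_interval(occ, lens, sz, pad = ceiling(0.3 * sz) + 100L)
        if (is.null(pl))
          stop_data("cannot place false positives without overlap")
        occ <- pl$occ
        id <- sprintf("fp_%s_%03d", cl, i)
        manifest[[length(manifest) + 1L]] <- data.frame(
          kind = "fp", id = id, chromosome = pl$chromosome,
          pos1 = pl$pos1, pos2 = pl$pos2, sv_type = tp, callers = cl,
          violation = "", stringsAsFactors = FALSE)
        calls[[length(calls) + 1L]] <- cbind(
          data.frame(caller = cl, kind = "fp", truth_id = id,
                     chromosome = pl$chromosome, pos1 = pl$pos1,
                     pos2 = pl$pos2, sv_type = tp, violation = "",
                     stringsAsFactors = FALSE),
          sim_support(cl, 1L))
      }
    }

    # sub-threshold records: filtered on read, so placement is free
    if (sub_threshold_frac > 0) {
      for (cl in callers) {
        n_cl <- sum(vapply(calls, function(x) x$caller[1L] == cl, TRUE))
        n_sub <- ceiling(sub_threshold_frac * n_cl)
        viols <- sub_violations(cl, max(lens))
        for (i in seq_len(n_sub)) {
          v <- sample(viols, 1L)
          sz <- switch(v, size_small = sample(10:99, 1L),
                       size_large = 10000001L + sample(1:100000, 1L),
                       sample(200:5000, 1L))
          ok_ch <- names(lens)[lens > sz + 2]
          ch <- sample(ok_ch, 1L)
          p1 <- sample(seq(2L, as.integer(lens[[ch]] - sz)), 1L)
          sup <- sim_violation(cl, v)
          id <- sprintf("sub_%s_%03d", cl, i)
          tp <- sample(CALLER_TYPES[[cl]], 1L)
          manifest[[length(manifest) + 1L]] <- data.frame(
            kind = "subthreshold", id = id, chromosome = ch, pos1 = p1,
            pos2 = p1 + sz - 1L, sv_type = tp, callers = cl,
            violation = v, stringsAsFactors = FALSE)
          calls[[length(calls) + 1L]] <- cbind(
            data.frame(caller = cl, kind = "subthreshold", truth_id = id,
                       chromosome = ch, pos1 = p1, pos2 = p1 + sz - 1L,
                       sv_type = tp, violation = v,
                       stringsAsFactors = FALSE),
            sup)
        }
      }
    }

    calls <- do.call(rbind, c(lapply(calls, pad_support_cols),
                              list(make.row.names = FALSE)))
    manifest <- do.call(rbind, manifest)
    calls <- calls[order(calls$caller, calls$chromosome, calls$pos1), ,
                   drop = FALSE]
    rownames(calls) <- NULL

    for (cl in callers)
      write_caller_dialect(cl, calls[calls$caller == cl, , drop = FALSE],
                           out_dir)
    calls$support <- support_info_string(calls)
    keep_cols <- c("caller", "kind", "truth_id", "chromosome", "pos1",
                   "pos2", "sv_type", "support", "violation")
    calls_out <- calls[, keep_cols]
    manifest_path <- file.path(out_dir, "manifest.tsv")
    calls_path <- file.path(out_dir, "calls.tsv")
    utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(calls_out, calls_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(list(manifest = manifest, calls = calls_out,
                   manifest_path = manifest_path, calls_path = calls_path,
                   out_dir = out_dir))
  })
}

SUPPORT_COLS <- c("score", "pe", "sr", "su", "nsc", "nrp", "rd",
                  "e1", "e2", "e3", "e4")

pad_support_cols <- function(df) {
  for (cc in SUPPORT_COLS) if (is.null(df[[cc]])) df[[cc]] <- NA_real_
  df
}

# the info string each reader will reconstruct for this record
support_info_string <- function(df) {
  out <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    out[i] <- switch(df$caller[i],
      breakdancer = sprintf("score=%g;PE=%g", df$score[i], df$pe[i]),
      pindel = sprintf("SR=%g;score=%g", df$sr[i], df$score[i]),
      cnvnator = sprintf("eval1=%s;eval2=%s;eval3=%s;eval4=%s",
                         format(df$e1[i], trim = TRUE),
                         format(df$e2[i], trim = TRUE),
                         format(df$e3[i], trim = TRUE),
                         format(df$e4[i], trim = TRUE)),
      delly = sprintf("PE=%g;SR=%g", df$pe[i], df$sr[i]),
      svseq = sprintf("SR=%g", df$sr[i]),
      lumpy = sprintf("SU=%g", df$su[i]),
      softsearch = sprintf("nSC=%g;nRP=%g", df$nsc[i], df$nrp[i]))
  }
  out
}

# ---- dialect writers ---------------------------------------------------

write_caller_dialect <- function(caller, df, out_dir) {
  switch(caller,
    breakdancer = {
      lines <- c(paste0("#Chr1\tPos1\tOrientation1\tChr2\tPos2\t",
                        "Orientation2\tType\tSize\tScore\tnum_Reads"),
                 sprintf("%s\t%d\t%s\t%s\t%d\t%s\t%s\t%d\t%g\t%g",
                         df$chromosome, df$pos1, "5+5-", df$chromosome,
                         df$pos2, "5+5-",
                         c(del = "DEL", inv = "INV")[df$sv_type],
                         df$pos2 - df$pos1 + 1L, df$score, df$pe))
      writeLines(lines, file.path(out_dir, "breakdancer.txt"))
    },
    pindel = {
      dir.create(file.path(out_dir, "pindel"), showWarnings = FALSE)
      lab <- c(del = "D", dup = "TD", inv = "INV")
      for (tp in c("del", "dup", "inv")) {
        sub <- df[df$sv_type == tp, , drop = FALSE]
        path <- file.path(out_dir, "pindel", paste0("sim_", lab[[tp]]))
        lines <- character()
        for (i in seq_len(nrow(sub))) {
          hdr <- sprintf(paste0("%d\t%s %d\tNT 0 \"\"\tChrID %s\t",
                                "BP %d\t%d\tBP_range %d\t%d\t",
                                "Supports %g\t%g\tS1 %g"),
                         i - 1L, lab[[tp]], sub$pos2[i] - sub$pos1[i] + 1L,
                         sub$chromosome[i], sub$pos1[i] - 1L,
                         sub$pos2[i] + 1L, sub$pos1[i] - 1L,
                         sub$pos2[i] + 1L, sub$sr[i], sub$sr[i],
                         sub$score[i])
          lines <- c(lines, strrep("#", 30), hdr)
        }
        writeLines(lines, path)
      }
    },
    cnvnator = {
      dir.create(file.path(out_dir, "cnvnator"), showWarnings = FALSE)
      lab <- c(del = "deletion", dup = "duplication")
      for (ch in unique(df$chromosome)) {
        sub <- df[df$chromosome == ch, , drop = FALSE]
        lines <- sprintf("%s\t%s:%d-%d\t%d\t%g\t%s\t%s\t%s\t%s\t0",
                         lab[sub$sv_type], ch, sub$pos1, sub$pos2,
                         sub$pos2 - sub$pos1, sub$rd,
                         format(sub$e1, trim = TRUE),
                         format(sub$e2, trim = TRUE),
                         format(sub$e3, trim = TRUE),
                         format(sub$e4, trim = TRUE))
        writeLines(lines, file.path(out_dir, "cnvnator",
                                    paste0(ch, ".txt")))
      }
    },
    delly = write_sim_vcf(df, file.path(out_dir, "delly.vcf"),
                          c(PE = "pe", SR = "sr")),
    lumpy = write_sim_vcf(df, file.path(out_dir, "lumpy.vcf"),
                          c(SU = "su")),
    softsearch = write_sim_vcf(df, file.path(out_dir, "softsearch.vcf"),
                               c(nSC = "nsc", nRP = "nrp")),
    svseq = {
      dir.create(file.path(out_dir, "svseq"), showWarnings = FALSE)
      for (ch in unique(df$chromosome)) {
        sub <- df[df$chromosome == ch, , drop = FALSE]
        writeLines(sprintf("%d\t%d\t%g", sub$pos1, sub$pos2, sub$sr),
                   file.path(out_dir, "svseq", paste0(ch, ".del")))
      }
    })
  invisible(NULL)
}

write_sim_vcf <- function(df, path, keys) {
  info_defs <- vapply(names(keys), function(k)
    sprintf("##INFO=<ID=%s,Number=1,Type=Integer,Description=\"%s\">",
            k, k), "")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=svintegrate-simulator",
           paste0("##INFO=<ID=SVTYPE,Number=1,Type=String,",
                  "Description=\"SV type\">"),
           paste0("##INFO=<ID=END,Number=1,Type=Integer,",
                  "Description=\"End of the variant\">"),
           info_defs,
           "##ALT=<ID=DEL,Description=\"Deletion\">",
           "##ALT=<ID=DUP,Description=\"Duplication\">",
           "##ALT=<ID=INV,Description=\"Inversion\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  extra <- vapply(seq_len(nrow(df)), function(i)
    paste(sprintf("%s=%d", names(keys),
                  as.integer(unlist(df[i, keys]))), collapse = ";"), "")
  alt <- c(del = "<DEL>", dup = "<DUP>", inv = "<INV>")[df$sv_type]
  body <- sprintf("%s\t%d\tsv%05d\tN\t%s\t.\tPASS\tSVTYPE=%s;END=%d;%s",
                  df$chromosome, df$pos1 - 1L, seq_len(nrow(df)), alt,
                  toupper(df$sv_type), df$pos2, extra)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read the simulated caller outputs of a fixture directory
#'
#' Convenience wrapper mapping each caller name to its reader and the
#' file layout produced by [emit_caller_outputs()].
#'
#' @param out_dir Fixture directory.
#' @param callers Callers to read.
#' @param params [merge_params()].
#' @param keep_all Passed through to the readers.
#' @return Named list of `CallSet` objects.
#' @export
read_simulated <- function(out_dir, callers, params = merge_params(),
                           keep_all = FALSE) {
  paths <- list(breakdancer = file.path(out_dir, "breakdancer.txt"),
                pindel = file.path(out_dir, "pindel"),
                cnvnator = file.path(out_dir, "cnvnator"),
                delly = file.path(out_dir, "delly.vcf"),
                lumpy = file.path(out_dir, "lumpy.vcf"),
                softsearch = file.path(out_dir, "softsearch.vcf"),
                svseq = file.path(out_dir, "svseq"))
  out <- lapply(callers, function(cl)
    caller_reader(cl)(paths[[cl]], params = params, keep_all = keep_all))
  names(out) <- callers
  out
}

#' Score merged SVs against the planted truth
#'
#' A merged SV matches a truth SV when both have the same type and
#' chromosome and reciprocal overlap strictly above
#' `params$overlap_frac`; candidate pairs are assigned greedily by
#' descending overlap, one-to-one.
#'
#' @param merged A `MergedSVList`.
#' @param manifest Manifest data frame (or path to `manifest.tsv`) from
#'   [emit_caller_outputs()].
#' @param params [merge_params()].
#' @return List with `precision`, `recall`, `mean_boundary_error` (mean
#'   over matches of the two absolute breakpoint offsets), counts, and
#'   the per-match table.
#' @export
evaluate_against_truth <- function(merged, manifest,
                                   params = merge_params()) {
  if (is.character(manifest))
    manifest <- utils::read.table(manifest, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
  truth <- manifest[manifest$kind == "truth", , drop = FALSE]
  matches <- list(); n_merged <- 0L
  for (tp in SV_TYPES) {
    m <- merged[[tp]]; t <- truth[truth$sv_type == tp, , drop = FALSE]
    if (is.null(m)) m <- empty_records()[, c("chromosome", "pos1", "pos2")]
    n_merged <- n_merged + nrow(m)
    if (!nrow(m) || !nrow(t)) next
    pairs <- expand.grid(mi = seq_len(nrow(m)), ti = seq_len(nrow(t)))
    pairs <- pairs[m$chromosome[pairs$mi] == t$chromosome[pairs$ti], ,
                   drop = FALSE]
    if (!nrow(pairs)) next
    pairs$ro <- reciprocal_overlap(m$pos1[pairs$mi], m$pos2[pairs$mi],
                                   t$pos1[pairs$ti], t$pos2[pairs$ti])
    pairs <- pairs[pairs$ro > params$overlap_frac, , drop = FALSE]
    pairs <- pairs[order(-pairs$ro), , drop = FALSE]
    used_m <- logical(nrow(m)); used_t <- logical(nrow(t))
    for (k in seq_len(nrow(pairs))) {
      mi <- pairs$mi[k]; ti <- pairs$ti[k]
      if (used_m[mi] || used_t[ti]) next
      used_m[mi] <- TRUE; used_t[ti] <- TRUE
      matches[[length(matches) + 1L]] <- data.frame(
        sv_type = tp, truth_id = t$id[ti], chromosome = t$chromosome[ti],
        truth_pos1 = t$pos1[ti], truth_pos2 = t$pos2[ti],
        merged_pos1 = m$pos1[mi], merged_pos2 = m$pos2[mi],
        ro = pairs$ro[k], stringsAsFactors = FALSE)
    }
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(sv_type = character(), truth_id = character(),
               chromosome = character(), truth_pos1 = numeric(),
               truth_pos2 = numeric(), merged_pos1 = numeric(),
               merged_pos2 = numeric(), ro = numeric(),
               stringsAsFactors = FALSE)
  be <- if (nrow(matches))
    mean(c(abs(matches$merged_pos1 - matches$truth_pos1),
           abs(matches$merged_pos2 - matches$truth_pos2))) else NA_real_
  list(precision = if (n_merged) nrow(matches) / n_merged else NA_real_,
       recall = if (nrow(truth)) nrow(matches) / nrow(truth) else NA_real_,
       mean_boundary_error = be, n_merged = n_merged,
       n_truth = nrow(truth), matches = matches)
}
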