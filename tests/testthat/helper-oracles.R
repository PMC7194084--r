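# Shared fixtures and independent brute-force oracles.  The oracles never
# call the code paths they check: per-base interval arithmetic, BFS
# connected components over an explicitly materialized overlap graph, and
# all-pairs intersection scans.

# per-base reciprocal overlap: count shared integer positions explicitly
oracle_ro <- function(a1, a2, b1, b2) {
  o <- length(intersect(seq(a1, a2), seq(b1, b2)))
  min(o / length(seq(a1, a2)), o / length(seq(b1, b2)))
}

# connected components of the RO > frac graph via breadth-first search
# over an explicit adjacency matrix
oracle_components <- function(records, frac) {
  n <- nrow(records)
  if (n == 0L) return(integer())
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (records$chromosome[i] != records$chromosome[j]) next
    adj[i, j] <- oracle_ro(records$pos1[i], records$pos2[i],
                           records$pos1[j], records$pos2[j]) > frac
  }
  comp <- rep(NA_integer_, n); k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# partitions as canonical sets-of-sets, for label-free comparison
partition_sets <- function(ids) unname(lapply(split(seq_along(ids), ids), sort))
same_partition <- function(a, b) {
  setequal(lapply(partition_sets(a), paste, collapse = ","),
           lapply(partition_sets(b), paste, collapse = ","))
}

# all-pairs (SV x element) intersection scan
oracle_annotate <- function(sv, elements) {
  rows <- list()
  for (i in seq_len(nrow(sv))) {
    hit <- FALSE
    for (j in seq_len(nrow(elements))) {
      if (sv$chromosome[i] != elements$chromosome[j]) next
      if (max(sv$pos1[i], elements$start[j]) >
          min(sv$pos2[i], elements$end[j])) next
      hit <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        sv = i, tag = elements$tag[j], start = elements$start[j],
        end = elements$end[j], ID = elements$ID[j],
        stringsAsFactors = FALSE)
    }
    if (!hit)
      rows[[length(rows) + 1L]] <- data.frame(
        sv = i, tag = "", start = NA_real_, end = NA_real_, ID = "",
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# random same-type record tables for clustering properties
rand_records <- function(n, n_chrom = 2L, max_pos = 2000L) {
  p1 <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(300L, n, replace = TRUE)
  data.frame(chromosome = sprintf("chr%d", sample.int(n_chrom, n, TRUE)),
             pos1 = p1, pos2 = p1 + len,
             size = NA_real_,
             info = sprintf("SU=%d", sample.int(50L, n, TRUE)),
             stringsAsFactors = FALSE)
}

# compact CallSet builder for merge tests
mk_callset <- function(caller, del = NULL, dup = NULL, inv = NULL) {
  fix <- function(df) {
    if (is.null(df)) return(NULL)
    if (is.null(df$size)) df$size <- NA_real_
    if (is.null(df$info)) df$info <- "SU=5"
    df
  }
  callset(caller, Filter(Negate(is.null),
                         list(del = fix(del), dup = fix(dup),
                              inv = fix(inv))))
}

rec <- function(chromosome, pos1, pos2, size = NA_real_, info = "SU=5") {
  data.frame(chromosome = chromosome, pos1 = pos1, pos2 = pos2,
             size = size, info = info, stringsAsFactors = FALSE)
}

# standard small fixture set shared by several test files
fixture_dir <- function(seed = 42L, n_per_type = c(del = 15, dup = 8,
                                                   inv = 6),
                        callers = c("breakdancer", "pindel", "cnvnator",
                                    "delly", "lumpy"),
                        fp_per_caller = 5L, sub_threshold_frac = 0,
                        jitter_frac = 0.05) {
  spec <- genome_spec()
  truth <- simulate_truth(spec, n_per_type = n_per_type, seed = seed)
  dir <- tempfile("svfix")
  res <- emit_caller_outputs(truth, spec, callers = callers,
                             jitter_frac = jitter_frac,
                             fp_per_caller = fp_per_caller,
                             sub_threshold_frac = sub_threshold_frac,
                             out_dir = dir, seed = seed + 1L)
  list(spec = spec, truth = truth, dir = dir, res = res,
       callers = callers)
}
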