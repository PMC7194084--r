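# Genome-wide SV density (windowed counts rendered as a circular or
# linear bar plot) and per-region SV/gene track plots.  Colors follow the
# genome-plot convention: deletions blue, duplications red, inversions
# green; in region plots genes are blue, deletions red, duplications
# green.

SV_COLORS <- c(del = "#2166ac", dup = "#b2182b", inv = "#1b7837")
REGION_COLORS <- c(gene = "#2166ac", del = "#b2182b", dup = "#1b7837",
                   inv = "#e08214")

#' Windowed SV counts along the genome
#'
#' Chromosomes are tiled with non-overlapping windows of `window` bp (the
#' last window truncated at the chromosome end) and each SV is assigned to
#' exactly one window — the one containing its midpoint — so per-type
#' window sums equal the input SV counts.
#'
#' @param merged A `MergedSVList` (or a single data frame plus `sv_type`).
#' @param chrom_sizes Named vector of chromosome lengths
#'   ([read_chrom_sizes()]).
#' @param window Window size in bp, default 1e6.
#' @param sv_type SV type label when `merged` is a single data frame.
#' @return Data frame `chromosome`, `window_start`, `window_end`, `del`,
#'   `dup`, `inv`.
#' @export
window_counts <- function(merged, chrom_sizes, window = 1e6,
                          sv_type = NULL) {
  if (window <= 0) stop_config("window must be positive")
  if (is.data.frame(merged)) {
    merged <- stats::setNames(list(merged), sv_type %||% "del")
  }
  wc <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    ws <- seq(1, len, by = window)
    data.frame(chromosome = ch, window_start = ws,
               window_end = pmin(ws + window - 1, len),
               stringsAsFactors = FALSE)
  }))
  for (tp in SV_TYPES) wc[[tp]] <- 0L
  for (tp in names(merged)) {
    df <- merged[[tp]]
    if (is.null(df) || !nrow(df)) next
    unknown <- setdiff(unique(df$chromosome), names(chrom_sizes))
    if (length(unknown))
      stop_data("SV(s) on chromosome(s) absent from the sizes table: ",
                paste(unknown, collapse = ", "))
    mid <- floor((df$pos1 + df$pos2) / 2)
    mid <- pmin(pmax(mid, 1), chrom_sizes[df$chromosome])
    idx <- (mid - 1) %/% window
    key <- paste0(df$chromosome, ":", idx)
    wkey <- paste0(wc$chromosome, ":", (wc$window_start - 1) %/% window)
    tab <- table(key)
    hit <- match(names(tab), wkey)
    wc[[tp]][hit] <- wc[[tp]][hit] + as.integer(tab)
  }
  rownames(wc) <- NULL
  wc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a ggplot to .png or .svg with an explicit device so that two
# renders of identical input are byte-identical
save_plot <- function(p, out, width = 8, height = 8) {
  ext <- tolower(tools::file_ext(out))
  if (ext == "png") {
    grDevices::png(out, width = width, height = height, units = "in",
                   res = 150)
  } else if (ext == "svg") {
    grDevices::svg(out, width = width, height = height)
  } else {
    stop_config("unsupported image format: .", ext)
  }
  on.exit(grDevices::dev.off())
  print(p)
  invisible(out)
}

#' Genome-wide SV density plot
#'
#' One track per SV type, one bar per window; chromosomes are laid out
#' around a circle (`style = "circular"`, the default) or as stacked
#' panels (`style = "linear"`).  Bar heights within a track are scaled to
#' the track's maximum count.
#'
#' @param wc Window counts from [window_counts()].
#' @param style `"circular"` or `"linear"`.
#' @param out Output image path (`.png` or `.svg`).
#' @param colors Named colors per SV type.
#' @return The ggplot object, invisibly; the image is written to `out`.
#' @export
plot_genome <- function(wc, style = c("circular", "linear"), out,
                        colors = SV_COLORS) {
  style <- match.arg(style)
  if (!nrow(wc)) stop_data("no windows to plot")
  long <- do.call(rbind, lapply(SV_TYPES, function(tp)
    data.frame(chromosome = wc$chromosome,
               window_start = wc$window_start,
               window_end = wc$window_end,
               sv_type = tp, count = wc[[tp]],
               stringsAsFactors = FALSE)))
  long$sv_type <- factor(long$sv_type, levels = SV_TYPES)
  if (style == "linear") {
    long$mid <- (long$window_start + long$window_end) / 2 / 1e6
    p <- ggplot2::ggplot(long,
           ggplot2::aes(x = .data$mid, y = .data$count,
                        fill = .data$sv_type)) +
      ggplot2::geom_col(position = "dodge", width = diff(range(
        long$mid))[1] / max(length(unique(long$window_start)), 1) * 0.9) +
      ggplot2::facet_grid(sv_type ~ chromosome, scales = "free_x",
                          space = "free_x") +
      ggplot2::scale_fill_manual(values = colors, name = "SV type") +
      ggplot2::labs(x = "Position (Mb)", y = "SVs per window") +
      ggplot2::theme_bw()
  } else {
    chroms <- unique(wc$chromosome)
    sizes <- vapply(chroms, function(ch)
      max(wc$window_end[wc$chromosome == ch]), numeric(1))
    gap <- 0.01 * sum(sizes)
    offset <- stats::setNames(cumsum(c(0, sizes[-length(sizes)] + gap)),
                              chroms)
    long$x <- offset[long$chromosome] +
      (long$window_start + long$window_end) / 2
    long$w <- long$window_end - long$window_start + 1
    track_base <- stats::setNames((seq_along(SV_TYPES) - 1) * 1.4, SV_TYPES)
    maxc <- vapply(SV_TYPES, function(tp)
      max(long$count[long$sv_type == tp], 1), numeric(1))
    long$y0 <- track_base[as.character(long$sv_type)]
    long$y1 <- long$y0 + 1.2 * long$count /
      maxc[as.character(long$sv_type)]
    labs <- data.frame(x = offset + sizes / 2, chromosome = chroms)
    p <- ggplot2::ggplot(long) +
      ggplot2::geom_rect(ggplot2::aes(xmin = .data$x - .data$w / 2,
                                      xmax = .data$x + .data$w / 2,
                                      ymin = .data$y0, ymax = .data$y1,
                                      fill = .data$sv_type)) +
      ggplot2::geom_text(data = labs,
                         ggplot2::aes(x = .data$x, y = 4.6,
                                      label = .data$chromosome),
                         size = 3) +
      ggplot2::scale_fill_manual(values = colors, name = "SV type") +
      ggplot2::ylim(-2, 5) +
      ggplot2::coord_polar(theta = "x") +
      ggplot2::theme_void()
  }
  save_plot(p, out)
  invisible(p)
}

#' Plot SVs and gene models in a genomic region
#'
#' Draws the gene elements and merged SVs intersecting
#' `"chrom:start-end"` as labeled rectangles on separate tracks; features
#' extending past the region boundary are clipped, not dropped.
#'
#' @param merged A `MergedSVList`.
#' @param elements Gene elements from [read_gene_models()] (may have zero
#'   rows).
#' @param region Region string `"chrom:start-end"`.
#' @param out Output image path (`.png` or `.svg`).
#' @param colors Named colors for `gene` and the SV types.
#' @return The ggplot object, invisibly.
#' @export
plot_region <- function(merged, elements, region, out,
                        colors = REGION_COLORS) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
  if (length(m) != 4L) stop_config("malformed region string: ", region)
  chrom <- m[2L]; rs <- as.numeric(m[3L]); re <- as.numeric(m[4L])
  if (!(rs < re)) stop_config("region start must be below region end")
  known <- unique(c(elements$chromosome,
                    unlist(lapply(merged, function(df) df$chromosome))))
  if (!chrom %in% known)
    stop_data("region on unknown chromosome: ", chrom)

  clip1 <- function(s, e) list(s = pmax(s, rs), e = pmin(e, re))
  feats <- list()
  g <- elements[elements$tag == "gene" & elements$chromosome == chrom &
                  elements$start <= re & elements$end >= rs, , drop = FALSE]
  if (nrow(g)) {
    cc <- clip1(g$start, g$end)
    feats[[1L]] <- data.frame(kind = "gene", xmin = cc$s, xmax = cc$e,
                              label = g$ID, stringsAsFactors = FALSE)
  }
  for (tp in names(merged)) {
    df <- merged[[tp]]
    df <- df[df$chromosome == chrom & df$pos1 <= re & df$pos2 >= rs, ,
             drop = FALSE]
    if (!nrow(df)) next
    cc <- clip1(df$pos1, df$pos2)
    feats[[length(feats) + 1L]] <-
      data.frame(kind = tp, xmin = cc$s, xmax = cc$e,
                 label = df$methods, stringsAsFactors = FALSE)
  }
  feats <- if (length(feats)) do.call(rbind, feats) else
    data.frame(kind = character(), xmin = numeric(), xmax = numeric(),
               label = character(), stringsAsFactors = FALSE)
  tracks <- c("gene", SV_TYPES)
  ymap <- stats::setNames(rev(seq_along(tracks)), tracks)
  feats$ymin <- ymap[feats$kind] - 0.35
  feats$ymax <- ymap[feats$kind] + 0.35
  p <- ggplot2::ggplot() +
    ggplot2::scale_y_continuous(breaks = unname(ymap), labels = tracks,
                                limits = c(0.5, length(tracks) + 0.5)) +
    ggplot2::xlim(rs, re) +
    ggplot2::labs(x = paste0(chrom, " (bp)"), y = NULL, title = region) +
    ggplot2::theme_bw()
  if (nrow(feats)) {
    p <- p +
      ggplot2::geom_rect(data = feats,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                     ymin = .data$ymin, ymax = .data$ymax,
                     fill = .data$kind)) +
      ggplot2::geom_text(data = feats,
        ggplot2::aes(x = (.data$xmin + .data$xmax) / 2,
                     y = .data$ymax + 0.12, label = .data$label),
        size = 2.4) +
      ggplot2::scale_fill_manual(values = colors, guide = "none")
  }
  save_plot(p, out, width = 9, height = 4)
  invisible(p)
}
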