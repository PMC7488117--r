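# Localizing discordance along the genome: per-chromosome fractions,
# neighbor-distance pairs with a 2-D KDE, and sliding-window selection of
# compact validation regions.

#' Per-chromosome discordance fractions
#'
#' @param paired A paired-call tibble from [harmonize_pair()].
#' @return A tibble with one row per chromosome (`chrom, n_pairs,
#'   n_discordant, pct_discordant`; the percentage is `100 * n_discordant /
#'   n_pairs`), in canonical chromosome order. The genome-wide pooled
#'   fraction is attached as attribute `"overall"` and retrievable with
#'   [overall_discordance()].
#' @export
per_chromosome_discordance <- function(paired) {
  if (nrow(paired) == 0) {
    out <- tibble::tibble(chrom = character(), n_pairs = integer(),
                          n_discordant = integer(), pct_discordant = numeric())
    attr(out, "overall") <- list(n_pairs = 0L, n_discordant = 0L,
                                 pct_discordant = NA_real_)
    return(out)
  }
  out <- paired |>
    dplyr::group_by(chrom = .data$chrom) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     n_discordant = sum(!.data$concordant),
                     .groups = "drop") |>
    dplyr::mutate(pct_discordant = 100 * .data$n_discordant / .data$n_pairs)
  out <- out[chrom_order(out$chrom), ]
  attr(out, "overall") <- list(
    n_pairs = nrow(paired),
    n_discordant = sum(!paired$concordant),
    pct_discordant = 100 * sum(!paired$concordant) / nrow(paired)
  )
  out
}

#' @rdname per_chromosome_discordance
#' @param x The tibble returned by [per_chromosome_discordance()].
#' @export
overall_discordance <- function(x) {
  attr(x, "overall")
}

#' Neighbor-distance pairs of one variant group on one chromosome
#'
#' For each interior variant of a sorted position vector, the distances to
#' the previous and to the next variant of the same group; the first and
#' last variant have no pair. Plotted against each other (log-log), evenly
#' spread variants fall on the diagonal and the cloud's offset from it
#' reflects the group's density.
#'
#' @param positions Strictly increasing integer positions (bp).
#' @return A tibble `pos, d_prev, d_next`; empty for fewer than 3 positions.
#' @export
neighbor_distance_pairs <- function(positions) {
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  n <- length(positions)
  if (n < 3) {
    return(tibble::tibble(pos = integer(), d_prev = numeric(),
                          d_next = numeric()))
  }
  d <- diff(positions)
  tibble::tibble(pos = positions[2:(n - 1)],
                 d_prev = as.numeric(d[1:(n - 2)]),
                 d_next = as.numeric(d[2:(n - 1)]))
}

#' Distance-pair table for both concordance groups
#'
#' Applies [neighbor_distance_pairs()] per chromosome *within* each group
#' (concordant / discordant), so distances never straddle groups or
#' chromosomes.
#'
#' @param paired A paired-call tibble from [harmonize_pair()].
#' @return A tibble `chrom, pos, d_prev, d_next, group` with `group` in
#'   `{"CONCORDANT","DISCORDANT"}`. Also a convenient summary attribute
#'   `"bisectrix_offset"`: the mean |log10 d_prev - log10 d_next| per group,
#'   a simple evenness summary of the distance map.
#' @export
distance_pair_table <- function(paired) {
  grp <- ifelse(paired$concordant, "CONCORDANT", "DISCORDANT")
  pieces <- list()
  for (g in c("CONCORDANT", "DISCORDANT")) {
    sub <- paired[grp == g, ]
    for (ch in unique(sub$chrom)) {
      pos <- sort(unique(sub$pos[sub$chrom == ch]))
      dp <- neighbor_distance_pairs(pos)
      if (nrow(dp)) {
        dp$chrom <- ch
        dp$group <- g
        pieces[[length(pieces) + 1L]] <- dp
      }
    }
  }
  out <- if (length(pieces)) dplyr::bind_rows(pieces) else
    tibble::tibble(pos = integer(), d_prev = numeric(), d_next = numeric(),
                   chrom = character(), group = character())
  out <- out[, c("chrom", "pos", "d_prev", "d_next", "group")]
  off <- vapply(split(out, out$group), function(d) {
    mean(abs(log10(d$d_prev) - log10(d$d_next)))
  }, numeric(1))
  attr(out, "bisectrix_offset") <- off
  out
}

#' Gaussian kernel density estimate of a distance map
#'
#' 2-D Gaussian KDE of (d_prev, d_next) pairs on a log10-log10 grid.
#' Bandwidth defaults to Scott's rule for two dimensions
#' (\eqn{sd_i \cdot m^{-1/6}} per axis, on the log scale).
#'
#' @param d_prev,d_next Positive distances (bp); at least 2 pairs.
#' @param n_grid Grid points per axis.
#' @param bandwidth Optional length-2 numeric overriding Scott's rule
#'   (log10-scale standard deviations of the kernel).
#' @return A list `x, y, z, bandwidth` (`x`/`y` are log10 grid coordinates,
#'   `z` the density, integrating to ~1 over the grid).
#' @export
kde_density <- function(d_prev, d_next, n_grid = 100, bandwidth = NULL) {
  if (length(d_prev) != length(d_next)) {
    stop("d_prev and d_next differ in length", call. = FALSE)
  }
  if (length(d_prev) < 2) {
    stop("need at least 2 distance pairs for a density estimate",
         call. = FALSE)
  }
  lx <- log10(d_prev)
  ly <- log10(d_next)
  if (is.null(bandwidth)) {
    m <- length(lx)
    bandwidth <- c(stats::sd(lx), stats::sd(ly)) * m^(-1 / 6)
    bandwidth[bandwidth <= 0 | is.na(bandwidth)] <- 1e-3
  }
  pad <- 3 * bandwidth
  est <- MASS::kde2d(lx, ly, h = 4 * bandwidth, n = n_grid,
                     lims = c(range(lx) + c(-1, 1) * pad[1],
                              range(ly) + c(-1, 1) * pad[2]))
  list(x = est$x, y = est$y, z = est$z, bandwidth = bandwidth)
}

#' Select compact validation regions of discordant variants
#'
#' Greedy maximal cover with a bounded window: repeatedly choose the window
#' of span at most `max_span` containing the largest number of not-yet-covered
#' discordant sites (ties broken by leftmost window in canonical chromosome /
#' position order), emit the tight span of those sites as a region, and mark
#' them covered. Concordant sites falling inside a region's span are attached
#' to it. Spans this small are what a single Sanger read can cover, which is
#' the motivating constraint.
#'
#' @param discordant Tibble of discordant sites (`chrom, pos`, optionally
#'   `id`, `var_class`).
#' @param concordant Optional tibble of concordant sites, same columns.
#' @param max_span Maximum region span in bp (end - start), default 500.
#' @return A tibble `chrom, start, end, n_indel, n_snv, n_total` with
#'   list-columns `sites` (the covered discordant sites) and
#'   `concordant_sites`. `end - start <= max_span` for every region and no
#'   discordant site is covered twice.
#' @export
select_validation_regions <- function(discordant, concordant = NULL,
                                      max_span = 500) {
  if (is.null(discordant) || nrow(discordant) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_indel = integer(),
                          n_snv = integer(), n_total = integer(),
                          sites = list(), concordant_sites = list()))
  }
  d <- discordant
  if (!"var_class" %in% names(d)) d$var_class <- NA_character_
  if (!"id" %in% names(d)) d$id <- NA_character_
  d <- d[chrom_order(d$chrom), ]
  d <- d[order(match(d$chrom, unique(d$chrom)), d$pos), ]

  covered <- rep(FALSE, nrow(d))
  regions <- list()
  while (!all(covered)) {
    best_count <- 0L
    best_rows <- NULL
    for (i in which(!covered)) {
      in_win <- !covered & d$chrom == d$chrom[i] &
        d$pos >= d$pos[i] & d$pos <= d$pos[i] + max_span
      cnt <- sum(in_win)
      if (cnt > best_count) {  # ties keep the earlier (leftmost) window
        best_count <- cnt
        best_rows <- which(in_win)
      }
    }
    sites <- d[best_rows, ]
    covered[best_rows] <- TRUE
    start <- min(sites$pos)
    end <- max(sites$pos)
    conc <- NULL
    if (!is.null(concordant) && nrow(concordant)) {
      conc <- concordant[concordant$chrom == sites$chrom[1] &
                           concordant$pos >= start &
                           concordant$pos <= end, ]
    }
    regions[[length(regions) + 1L]] <- tibble::tibble(
      chrom = sites$chrom[1],
      start = as.integer(start), end = as.integer(end),
      n_indel = sum(sites$var_class == "INDEL", na.rm = TRUE),
      n_snv = sum(sites$var_class == "SNV", na.rm = TRUE),
      n_total = nrow(sites),
      sites = list(sites),
      concordant_sites = list(conc)
    )
  }
  dplyr::bind_rows(regions)
}

#' Write validation regions as a TSV or BED file
#'
#' The TSV mirrors the region-table layout (`Chromosome, Start, End, INDELs,
#' SNVs, Total`) with 1-based closed coordinates; the BED file is 0-based
#' half-open with the region index as name and the discordant-site count as
#' score.
#'
#' @param regions Output of [select_validation_regions()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_regions_tsv <- function(regions, path) {
  df <- data.frame(Chromosome = regions$chrom, Start = regions$start,
                   End = regions$end, INDELs = regions$n_indel,
                   SNVs = regions$n_snv, Total = regions$n_total,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_regions_tsv
#' @export
write_regions_bed <- function(regions, path) {
  df <- data.frame(regions$chrom, regions$start - 1L, regions$end,
                   paste0("region_", seq_len(nrow(regions))),
                   regions$n_total)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
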