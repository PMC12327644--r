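#' Fine-mapping regions around simulated causal variants
#'
#' One region per causal variant: the index window
#' `[c - half_width, c + half_width]` clipped to the panel ends, i.e. at most
#' `2 * half_width + 1` variants (1001 with the default; two-causal designs use
#' `half_width = 1000` for up-to-2001-variant regions). Simulation regions are
#' never merged, irrespective of overlap.
#'
#' @param truth causal-truth tibble with an `index` column (e.g.
#'   `sim$causal`), one region per row.
#' @param m_total total number of variants in the panel.
#' @param half_width variants to each side of the causal index.
#' @param ids optional variant ids (for `lead_id`).
#' @return tibble: region_id, causal_index, lead_id, start_index, end_index,
#'   n_snps.
#' @export
regions_from_causals <- function(truth, m_total, half_width = 500, ids = NULL) {
  idx <- truth$index
  start <- pmax(1L, idx - as.integer(half_width))
  end <- pmin(as.integer(m_total), idx + as.integer(half_width))
  tibble(region_id = sprintf("region%d", seq_along(idx)),
         causal_index = idx,
         lead_id = if (is.null(ids)) sprintf("snp%d", idx) else ids[idx],
         start_index = start, end_index = end, n_snps = end - start + 1L)
}

#' Fine-mapping regions around genome-wide significant lead SNPs
#'
#' Every genome-wide significant variant (p < `p_thresh`) spawns a 1 Mb window
#' (`flank_bp` to each side); windows on the same chromosome overlapping by
#' more than `merge_overlap_bp` are merged transitively, and a merged region
#' keeps its most significant variant as lead.
#'
#' @param ss a `blr_sumstats` tibble with sorted positions per chromosome.
#' @param p_thresh genome-wide significance threshold.
#' @param flank_bp half window width in basepairs.
#' @param merge_overlap_bp minimum shared span (bp) that triggers a merge.
#' @return tibble: region_id, chrom, start, end, lead_id, lead_pvalue, n_snps
#'   (coordinates 1-based inclusive). Empty tibble when nothing is significant.
#' @export
regions_from_leads <- function(ss, p_thresh = 5e-8, flank_bp = 5e5,
                               merge_overlap_bp = 5e5) {
  leads <- dplyr::filter(ss, .data$pvalue < p_thresh)
  if (nrow(leads) == 0)
    return(tibble(region_id = character(), chrom = character(),
                  start = double(), end = double(), lead_id = character(),
                  lead_pvalue = double(), n_snps = integer()))
  win <- leads |>
    dplyr::mutate(start = pmax(1, .data$pos - flank_bp),
                  end = .data$pos + flank_bp) |>
    dplyr::arrange(.data$chrom, .data$start)
  merged <- win |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      grp <- integer(nrow(d))
      g <- 1L
      grp[1] <- g
      for (i in seq_len(nrow(d))[-1]) {
        overlap <- min(d$end[i - 1], d$end[i]) - d$start[i]  # shared span
        if (overlap <= merge_overlap_bp) g <- g + 1L
        grp[i] <- g
        if (overlap > merge_overlap_bp) d$end[i] <- max(d$end[i - 1], d$end[i])
      }
      d$grp <- grp
      d |>
        dplyr::group_by(.data$grp) |>
        dplyr::summarise(start = min(.data$start), end = max(.data$end),
                         lead_id = .data$id[which.min(.data$pvalue)],
                         lead_pvalue = min(.data$pvalue), .groups = "drop")
    }) |>
    dplyr::ungroup()
  merged |>
    dplyr::mutate(region_id = sprintf("region%d", dplyr::row_number()),
                  n_snps = purrr::map2_int(.data$chrom, seq_len(nrow(merged)),
                    function(ch, i) sum(ss$chrom == ch & ss$pos >= merged$start[i] &
                                          ss$pos <= merged$end[i]))) |>
    dplyr::select("region_id", "chrom", "start", "end", "lead_id",
                  "lead_pvalue", "n_snps")
}

#' Simple credible set by cumulative PIP (CS1)
#'
#' Variants are sorted by descending PIP (ties broken by ascending position
#' order) and added greedily until the cumulative PIP reaches the coverage
#' threshold. If the total PIP mass in the region is below the threshold no set
#' is formed (`NULL`), which downstream scoring treats as a false negative.
#'
#' @param pips per-variant PIPs in the region.
#' @param ids optional variant ids.
#' @param coverage cumulative-PIP threshold (default 0.9).
#' @return tibble (id, index, pip, cum_pip) or `NULL`.
#' @export
cs1 <- function(pips, ids = NULL, coverage = 0.9) {
  stopifnot(all(pips >= 0 & pips <= 1))
  if (sum(pips) < coverage) return(NULL)
  ids <- ids %||% sprintf("v%d", seq_along(pips))
  ord <- order(-pips, seq_along(pips))
  cum <- cumsum(pips[ord])
  k <- which(cum >= coverage)[1]
  sel <- ord[seq_len(k)]
  tibble(id = ids[sel], index = sel, pip = pips[sel], cum_pip = cum[seq_len(k)])
}

#' Multiple LD-aware credible sets (CS2)
#'
#' Iterative procedure allowing several credible sets per region:
#' (1) variants with PIP <= `pip_floor` are dropped; (2) every variant with
#' PIP >= `coverage` is emitted as a single-SNP credible set and removed;
#' (3) the highest remaining PIP seeds a group of unassigned variants in strong
#' LD with it (r^2 >= `r2_min`); group members are sorted by PIP and
#' accumulated: if the cumulative PIP reaches `coverage` a set is emitted,
#' otherwise the seed group is discarded; (4) repeat until no seed can form a
#' set.
#'
#' @param pips per-variant PIPs.
#' @param B dense `ld_matrix` (or plain correlation matrix) aligned to `pips`;
#'   grouping uses the squared signed correlation.
#' @param ids optional ids.
#' @param coverage cumulative-PIP threshold.
#' @param r2_min LD threshold for grouping with the seed.
#' @param pip_floor drop variants at or below this PIP first (0 for
#'   simulations; 0.001 is the usual real-data floor).
#' @return tibble (cs_id, id, index, pip, cum_pip); zero rows if no set forms.
#' @export
cs2 <- function(pips, B, ids = NULL, coverage = 0.9, r2_min = 0.5,
                pip_floor = 0) {
  stopifnot(all(pips >= 0 & pips <= 1))
  R <- if (inherits(B, "ld_matrix")) as.matrix(B) else B
  stopifnot(nrow(R) == length(pips))
  ids <- ids %||% (if (inherits(B, "ld_matrix")) B$ids else sprintf("v%d", seq_along(pips)))
  avail <- which(pips > pip_floor)
  sets <- list()
  # single-SNP sets first
  singles <- avail[pips[avail] >= coverage]
  singles <- singles[order(-pips[singles], singles)]
  for (s in singles)
    sets[[length(sets) + 1L]] <- tibble(id = ids[s], index = s, pip = pips[s],
                                        cum_pip = pips[s])
  avail <- setdiff(avail, singles)
  # iterative seeded grouping
  while (length(avail) > 0) {
    seed <- avail[order(-pips[avail], avail)][1]
    grp <- avail[R[seed, avail]^2 >= r2_min]  # includes the seed (r = 1)
    grp <- grp[order(-pips[grp], grp)]
    cum <- cumsum(pips[grp])
    if (max(cum) >= coverage) {
      k <- which(cum >= coverage)[1]
      sel <- grp[seq_len(k)]
      sets[[length(sets) + 1L]] <- tibble(id = ids[sel], index = sel,
                                          pip = pips[sel],
                                          cum_pip = cum[seq_len(k)])
      avail <- setdiff(avail, sel)
    } else {
      avail <- setdiff(avail, seed)  # discard the seed, try the next one
    }
  }
  if (length(sets) == 0)
    return(tibble(cs_id = character(), id = character(), index = integer(),
                  pip = double(), cum_pip = double()))
  dplyr::bind_rows(purrr::imap(sets, function(s, i)
    dplyr::mutate(s, cs_id = sprintf("cs%d", i), .before = 1)))
}

#' Purity of a credible set
#'
#' Mean absolute pairwise correlation among the set's variants. Singleton sets
#' are not informative and return `NA`; sets larger than `max_snps` are
#' measured on a seeded random subsample of `max_snps` variants. The squared
#' version (mean pairwise r^2) is also returned.
#'
#' @param indices variant indices of the set's members.
#' @param B dense `ld_matrix` or correlation matrix.
#' @param max_snps subsample cap.
#' @param seed seed for the subsample.
#' @return list with `abs_r` (primary) and `r2`.
#' @export
purity <- function(indices, B, max_snps = 100, seed = NULL) {
  if (length(indices) < 2) return(list(abs_r = NA_real_, r2 = NA_real_))
  if (length(indices) > max_snps)
    indices <- with_seed(seed, sort(sample(indices, max_snps)))
  R <- if (inherits(B, "ld_matrix")) as.matrix(B) else B
  sub <- R[indices, indices, drop = FALSE]
  off <- sub[lower.tri(sub)]
  list(abs_r = mean(abs(off)), r2 = mean(off^2))
}

#' Summarise credible sets of one region
#'
#' @param cs_tbl output of [cs2()] (or [cs1()] with a `cs_id` added).
#' @param B dense LD for the purity statistics.
#' @param max_snps,seed passed to [purity()].
#' @return one row per set: cs_id, size, cum_pip, purity_abs_r, purity_r2.
#' @export
cs_summary <- function(cs_tbl, B, max_snps = 100, seed = NULL) {
  if (is.null(cs_tbl) || nrow(cs_tbl) == 0)
    return(tibble(cs_id = character(), size = integer(), cum_pip = double(),
                  purity_abs_r = double(), purity_r2 = double()))
  cs_tbl |>
    dplyr::group_by(.data$cs_id) |>
    dplyr::group_modify(function(d, key) {
      p <- purity(d$index, B, max_snps = max_snps, seed = seed)
      tibble(size = nrow(d), cum_pip = max(d$cum_pip),
             purity_abs_r = p$abs_r, purity_r2 = p$r2)
    }) |>
    dplyr::ungroup()
}

#' Region and credible-set TSV writers
#'
#' Regions use a BED-like layout with 1-based inclusive coordinates.
#'
#' @param x regions or credible-set tibble.
#' @param path file path.
#' @export
write_regions <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_regions
#' @export
write_credsets <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
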