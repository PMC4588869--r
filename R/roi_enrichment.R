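#' Assign 100-nt windows to promoter regions of interest
#'
#' Each window maps to the ROI it overlaps; a window overlapping several
#' ROIs is resolved to the gene with the nearest TSS (strand-aware: the ROI
#' start for `+` genes, the ROI end for `-` genes, unless a `tss` metadata
#' column is supplied). Windows overlapping no ROI map to `NA` and form the
#' "outside ROI" margin of the enrichment tables.
#'
#' @param windows `GRanges` of 100-nt windows.
#' @param rois `GRanges` of promoter spans with a `gene_id` metadata column
#'   and optionally `tss`.
#' @return Character vector of gene ids (or `NA`), one per window.
#' @export
assign_windows <- function(windows, rois) {
  stopifnot(methods::is(windows, "GRanges"), methods::is(rois, "GRanges"))
  if (is.null(S4Vectors::mcols(rois)$gene_id))
    stop("rois must carry a gene_id column")
  shared <- intersect(as.character(GenomeInfoDb::seqlevels(windows)),
                      as.character(GenomeInfoDb::seqlevels(rois)))
  if (length(shared) == 0 && length(windows) > 0 && length(rois) > 0)
    stop("no shared chromosome names between windows (",
         paste(GenomeInfoDb::seqlevels(windows), collapse = ","),
         ") and ROIs (",
         paste(GenomeInfoDb::seqlevels(rois), collapse = ","), ")")
  tss <- S4Vectors::mcols(rois)$tss
  if (is.null(tss)) {
    tss <- ifelse(as.character(GenomicRanges::strand(rois)) == "-",
                  GenomicRanges::end(rois), GenomicRanges::start(rois))
  }
  hits <- suppressWarnings(GenomicRanges::findOverlaps(windows, rois))
  out <- rep(NA_character_, length(windows))
  if (length(hits) == 0) return(out)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  mid <- (GenomicRanges::start(windows)[q] +
            GenomicRanges::end(windows)[q]) / 2
  d <- abs(mid - tss[s])
  ord <- order(q, d)                       # nearest TSS wins per window
  keep <- ord[!duplicated(q[ord])]
  out[q[keep]] <- S4Vectors::mcols(rois)$gene_id[s[keep]]
  out
}

check_table_counts <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("a, b, c, d must be non-negative integers")
  if (sum(counts) < 1)
    stop("need at least one window in the table")
}

#' Hypergeometric point probability of a 2x2 enrichment table
#'
#' The probability of observing exactly `a` significant windows inside the
#' ROI, given the table margins:
#' \deqn{P = \binom{a+b}{a} \binom{c+d}{c} / \binom{n}{a+c},\quad n = a+b+c+d}
#' with `a` = significant windows in the ROI, `b` = significant windows
#' outside, `c` = non-significant in the ROI, `d` = non-significant outside.
#' Computed in log space (`lchoose`) so large arrays cannot overflow.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return The point probability, in (0, 1].
#' @examples
#' roi_point_probability(1, 0, 0, 1)   # 0.5
#' @export
roi_point_probability <- function(a, b, c, d) {
  check_table_counts(a, b, c, d)
  n <- a + b + c + d
  exp(lchoose(a + b, a) + lchoose(c + d, c) - lchoose(n, a + c))
}

#' One-sided enrichment tail probability of a 2x2 table
#'
#' Sums the point probabilities over all tables with the same margins and
#' `a' >= a` — the Fisher-exact upper tail used to call enriched ROIs.
#'
#' @inheritParams roi_point_probability
#' @return The tail probability, in (0, 1]; always `>=` the point
#'   probability.
#' @export
roi_tail_probability <- function(a, b, c, d) {
  check_table_counts(a, b, c, d)
  row1 <- a + b; col1 <- a + c; n <- a + b + c + d
  a_max <- min(row1, col1)
  a_vals <- a:a_max
  sum(exp(lchoose(row1, a_vals) + lchoose(n - row1, col1 - a_vals) -
            lchoose(n, col1)))
}

#' Call differentially methylated regions of interest (DMROIs)
#'
#' For each ROI, builds the 2x2 table of window-level significance
#' (by default, robust-regression p < `sig_p` — the screen's trend test —
#' with `b`/`d` counted outside the ROI so the margins close), computes the
#' enrichment tail probability, tests ROI-aggregate methylation (per-sample
#' mean over informative member windows) between the extreme groups by
#' Mann-Whitney, and counts composite DMR calls among members. An ROI is a
#' DMROI when the enrichment tail p <= `enrich_p`, the extreme-group
#' Mann-Whitney p <= `mw_p`, and it contains at least one DMR.
#'
#' @param dmr_results A [call_dmrs()] result.
#' @param rois `GRanges` of ROIs with `gene_id` (see [assign_windows()]).
#' @param windows `GRanges` of the screened windows, in `dmr_results` row
#'   order.
#' @param methylation The regions x samples matrix the screen ran on.
#' @param design The [group_design()].
#' @param sig_p Window-level significance cut-off feeding the table (on
#'   `p_robust`, strict `<`).
#' @param enrich_p,mw_p DMROI cut-offs on the enrichment tail and the ROI
#'   Mann-Whitney p.
#' @param use_composite If `TRUE`, the table counts composite DMR calls
#'   instead of `p_robust < sig_p` windows.
#' @return A data frame of class `dmroi_results`, sorted by `p_tail`:
#'   `gene_id`, cell counts `a`, `b`, `c`, `d`, `n`, `p_point`, `p_tail`,
#'   `p_mw_roi`, `n_dmrs_in_roi`, `n_windows`, `is_dmroi`. ROIs with zero
#'   informative windows are excluded with a message.
#' @export
call_dmrois <- function(dmr_results, rois, windows, methylation, design,
                        sig_p = 0.01, enrich_p = 0.01, mw_p = 0.02,
                        use_composite = FALSE) {
  stopifnot(inherits(dmr_results, "dmr_results"),
            inherits(design, "group_design"),
            length(windows) == nrow(dmr_results),
            nrow(methylation) == nrow(dmr_results))
  gene <- assign_windows(windows, rois)
  info <- dmr_results$informative & !is.na(dmr_results$p_robust)
  sig <- if (use_composite) dmr_results$is_dmr
         else info & dmr_results$p_robust < sig_p
  sig[!info] <- FALSE

  n_sig_total <- sum(sig[info])
  n_info_total <- sum(info)
  groups <- unname(design$group_of)
  G <- design$n_groups
  i_lo <- which(groups == 1); i_hi <- which(groups == G)

  genes <- unique(gene[!is.na(gene)])
  rows <- lapply(genes, function(g) {
    member <- !is.na(gene) & gene == g
    m_info <- member & info
    if (!any(m_info)) return(NULL)
    a <- sum(sig & m_info)
    c_ <- sum(m_info) - a
    b <- n_sig_total - a
    d <- (n_info_total - sum(m_info)) - b
    roi_mean <- colMeans(methylation[m_info, , drop = FALSE])
    mw <- mann_whitney(roi_mean[i_lo], roi_mean[i_hi])
    data.frame(gene_id = g, a = a, b = b, c = c_, d = d,
               n = a + b + c_ + d,
               p_point = roi_point_probability(a, b, c_, d),
               p_tail = roi_tail_probability(a, b, c_, d),
               p_mw_roi = mw$p,
               n_dmrs_in_roi = sum(dmr_results$is_dmr & member),
               n_windows = sum(m_info),
               stringsAsFactors = FALSE)
  })
  dropped <- genes[vapply(rows, is.null, logical(1))]
  if (length(dropped) > 0)
    message("excluded ", length(dropped),
            " ROI(s) with zero informative windows: ",
            paste(head(dropped, 5), collapse = ", "))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no ROI with informative windows")
  out$is_dmroi <- out$p_tail <= enrich_p & out$p_mw_roi <= mw_p &
    out$n_dmrs_in_roi >= 1
  out <- out[order(out$p_tail, out$p_mw_roi), ]
  rownames(out) <- NULL
  class(out) <- c("dmroi_results", "data.frame")
  out
}

#' Gene-set enrichment of DMROI genes against the array background
#'
#' Upper-tail hypergeometric test per gene set: does the set contain more
#' DMROI genes than expected from drawing `length(dmroi_genes)` genes from
#' the array-design background? Set membership is intersected with the
#' background first. Benjamini-Hochberg adjusted p-values are added across
#' sets.
#'
#' @param dmroi_genes Character vector of DMROI gene ids (subset of
#'   `background`).
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param background Character vector: all genes on the array design.
#' @return Data frame sorted by `p_hyper`: `set_name`, `k_hit`, `set_size`,
#'   `n_dmroi_genes`, `background_size`, `p_hyper`, `p_bh`.
#' @export
geneset_enrichment <- function(dmroi_genes, sets, background) {
  background <- unique(as.character(background))
  if (length(background) == 0) stop("empty background")
  dmroi_genes <- unique(as.character(dmroi_genes))
  if (!all(dmroi_genes %in% background))
    stop("dmroi_genes must be a subset of the background")
  k_draw <- length(dmroi_genes)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(as.character(sets[[nm]])), background)
    k_hit <- length(intersect(members, dmroi_genes))
    p <- phyper(k_hit - 1, length(members),
                length(background) - length(members), k_draw,
                lower.tail = FALSE)
    data.frame(set_name = nm, k_hit = k_hit, set_size = length(members),
               n_dmroi_genes = k_draw, background_size = length(background),
               p_hyper = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- p.adjust(out$p_hyper, method = "BH")
  out[order(out$p_hyper), , drop = FALSE]
}
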