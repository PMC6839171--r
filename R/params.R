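#' Default pipeline parameters
#'
#' The fixed defaults of every stage: 100-bp bins, N = 5 flanking bins and
#' M = 100 trees for the classifiers, peak threshold 0.5 with 5-bin
#' expansion, minimum group difference w0 = 0.5, empirical p-value cutoff
#' P* = 0.05, 2-kb region merge distance, 12.5-kb peak cluster distance, and
#' a minimum enhancer-gene correlation of 0.9.
#'
#' @return named list of defaults
#' @export
defaultParams <- function() {
  list(bin_size = 100L,
       n_flank = 5L,
       n_trees = 100L,
       peak_threshold = 0.5,
       peak_flank = 5L,
       w0 = 0.5,
       p_star = 0.05,
       merge_gap = 2000L,
       max_gap = 12500L,
       r_min = 0.9)
}
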