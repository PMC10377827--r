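# shared builders and independent oracles for the test suite

# minimal panel: hemolysis pair + extra targets, two controls, one spike-in
tiny_panel <- function(extra_targets = c("hsa-miR-195-5p", "hsa-miR-1281")) {
  panel_definition(
    targets = c("hsa-miR-23a-3p", "hsa-miR-451a", extra_targets),
    endogenous_controls = c("SNORD61", "RNU6B"),
    spike_in = "cel-miR-39",
    hemolysis_pair = c("hsa-miR-23a-3p", "hsa-miR-451a"),
    name = "tiny")
}

# build a ct_matrix from a named list of per-sample profiles
tiny_ct <- function(profiles, groups, panel = NULL) {
  assays <- unique(unlist(lapply(profiles, names)))
  m <- sapply(profiles, function(p) p[assays])
  rownames(m) <- assays
  ct_matrix(m, groups, panel = panel)
}

# independent mean-subtraction oracle for global-mean normalization
oracle_global_dct <- function(ct, ct_max = 35) {
  keep <- !is.na(ct) & ct <= ct_max
  ct[keep] - sum(ct[keep]) / sum(keep)
}

# independent Kruskal-Wallis oracle: enumerate every group labelling via
# expand.grid, keep those with the observed group sizes, compute the
# tie-corrected H from first principles
oracle_kw_exact <- function(groups) {
  x <- unlist(groups)
  sizes <- lengths(groups)
  k <- length(sizes)
  n <- length(x)
  H_of <- function(lab) {
    r <- rank(x)
    s <- tapply(r, lab, sum)
    H <- 12 / (n * (n + 1)) * sum(s^2 / sizes[as.integer(names(s))]) - 3 * (n + 1)
    tie <- table(r)
    H / (1 - sum(tie^3 - tie) / (n^3 - n))
  }
  obs <- H_of(rep(seq_len(k), sizes))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  ok <- apply(grid, 1, function(lab) all(tabulate(lab, k) == sizes))
  hs <- apply(grid[ok, , drop = FALSE], 1, H_of)
  list(H = obs, p = mean(hs >= obs - 1e-12))
}

# closed-form fold regulation implied by a log2 effect
fr_closed_form <- function(e) ifelse(e >= 0, 2^e, -2^(-e))

# invert the signed fold-regulation convention back to log2 fold change;
# the continuous scale avoids the +1/-1 discontinuity at no change
fr_to_log2fc <- function(fr) sign(fr) * log2(abs(fr))

# records data.frame shorthand
rec_df <- function(ids, fr) {
  data.frame(mirna = ids, fold_regulation = fr, stringsAsFactors = FALSE)
}
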