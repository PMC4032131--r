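# shared fixtures: hand-built genealogies, small demographies, and a
# block-resampling standard error for tree-collection statistics

make_genealogy <- function(parent, time, roles,
                           labels = paste0(c("chimp", "nea", "afr",
                                             "eur")[roles + 1L],
                                           "_", seq_along(roles))) {
  structure(list(parent = as.integer(parent), time = as.numeric(time),
                 n_leaves = length(roles), leaf_role = as.integer(roles),
                 leaf_label = labels),
            class = "genealogy")
}

as_collection <- function(trees, roles) {
  structure(lapply(trees, function(t) list(parent = t$parent,
                                           time = t$time)),
            class = "genealogy_list",
            layout = list(role = as.integer(roles),
                          label = paste0("l", seq_along(roles))))
}

subset_trees <- function(trees, idx) {
  structure(unclass(trees)[idx], class = "genealogy_list",
            layout = attr(trees, "layout"))
}

block_se <- function(trees, stat, n_blocks = 20) {
  blocks <- split(seq_along(trees), rep(seq_len(n_blocks),
                                        length.out = length(trees)))
  v <- vapply(blocks, function(ix) stat(subset_trees(trees, ix)), 0)
  stats::sd(v) / sqrt(n_blocks)
}

# panmictic clean-split model with every population at the same size: the
# no-structure, no-admixture null
null_model_params <- function(n = 10000) {
  admixture_params(f = 0, n_anc = n, n_afr = n, n_eur = n, n_nea = n,
                   n_bottleneck = n)
}

small_null_params <- function() null_model_params(1000)
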