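# fixtures are built in code; no binary data anywhere

# minimal atlas with n regions named R01..Rnn (or custom labels)
tiny_atlas <- function(n = 4, labels = sprintf("R%02d", seq_len(n))) {
    new("RegionAtlas", regions = data.frame(
        index = seq_len(n), name = paste("region", seq_len(n)),
        x = as.numeric(seq_len(n)), y = -as.numeric(seq_len(n)),
        z = rep(0, n),
        hemisphere = rep(c("left", "right"), length.out = n),
        label = labels, stringsAsFactors = FALSE))
}

# random symmetric weight matrix in [0,1], zero diagonal, given edge density
random_weights <- function(n, density = 0.7, seed = 1) {
    set.seed(seed)
    w <- matrix(0, n, n)
    up <- which(upper.tri(w))
    on <- sample(c(TRUE, FALSE), length(up), replace = TRUE,
        prob = c(density, 1 - density))
    w[up[on]] <- runif(sum(on), 0.05, 1)
    w <- w + t(w)
    dimnames(w) <- list(sprintf("R%02d", 1:n), sprintf("R%02d", 1:n))
    w
}

random_graph <- function(n, density = 0.7, seed = 1) {
    connectivityGraph(random_weights(n, density, seed), tiny_atlas(n))
}

# cohort built from an explicit subjects x regions matrix
cohort_from_matrix <- function(values, group = "G",
                               atlas = tiny_atlas(ncol(values))) {
    colnames(values) <- regionLabels(atlas)
    MetabolicCohort(values, rep(group, length.out = nrow(values)), atlas)
}

write_cohort_file <- function(cohort, path = tempfile(fileext = ".tsv")) {
    writeCohort(cohort, path)
    path
}
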