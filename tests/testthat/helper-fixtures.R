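# small in-code fixtures shared across test files

toyMatrix <- function(nr = 3, nc = 2, seed = 1) {
    set.seed(seed)
    matrix(round(stats::runif(nr * nc, 1, 100), 3), nr, nc,
           dimnames = list(sprintf("p%d", seq_len(nr)),
                           sprintf("s%d", seq_len(nc))))
}

toyCohort <- function(m = toyMatrix(), scale = "log2", ...) {
    ExpressionCohort(m, datasetId = "toy", scale = scale, ...)
}

toyProbeMap <- function() {
    data.frame(probe_id = c("p1", "p2", "p3"),
               gene_symbol = c("GA", "GA", "GB"),
               isoform_label = c("iso1", "iso2", "iso1"),
               stringsAsFactors = FALSE)
}

# cohort whose two genes have known per-sample collapsed signals
twoGeneCohort <- function(tissue = rep("primary_tumor", 4)) {
    m <- rbind(p1 = c(2, 4, 6, 8), p2 = c(4, 6, 8, 10),
               p3 = c(1, 2, 3, 4))
    colnames(m) <- sprintf("s%d", 1:4)
    ExpressionCohort(m, "twogene", scale = "log2",
                     colData = data.frame(tissue_class = tissue,
                                          row.names = colnames(m)))
}
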