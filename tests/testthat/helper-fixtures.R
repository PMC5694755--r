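# Shared fixtures built in code at test time.

write_tsv_fixture <- function(df, dir = tempdir()) {
  path <- tempfile(fileext = ".tsv", tmpdir = dir)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Motif families mimicking CDR3 anatomy: conserved C prefix, variable
# centre, conserved F/W-bearing suffix.
base_family <- function() {
  motif_family("CAASAYQLIWG", variable = 2:6, sub_rate = 0.8,
               indel_prob = 0.2, name = "base")
}

tight_family <- function() {
  motif_family("CAASNTGGLSGKLTFG", variable = c(5, 7), sub_rate = 0.4,
               indel_prob = 0, name = "excl")
}

# A shared-suffix motif set: 20 length-11 CDR3s whose 6th-11th positions
# carry a fixed YQLIWG-type consensus, the situation the position-frequency
# matrix is meant to expose.
shared_suffix_set <- function() {
  c("CAASAYQLIWG", "CAASCYQLIWG", "CAASRYQLIWG", "CAASTYQLIWG",
    "CAARNYQLIWG", "CAAGNYQLIWG", "CAAADYQLIWG", "CAANNYQLIWG",
    "CAASDYQLIWG", "CAASNYQLIWG", "CAATNYQLIWG", "CAARDYQLIWG",
    "CADSNYQLIWG", "CAGSNYQLIWG", "CAGGNYQLIWG", "CASSNYQLIWG",
    "CATSNYQLIWG", "CAVSNYQLIWG", "CGGSNYQLIWG", "CVGSNYQLIWG")
}

# Tiny density_grid pair on a hand-made grid, for divergence unit tests.
toy_density_pair <- function(p, q) {
  nb <- length(p)
  g <- structure(list(edges = list(seq(0, nb, by = 1)),
                      centers = list(seq(0.5, nb - 0.5, by = 1)),
                      bins = as.integer(nb), dim = 1L),
                 class = "embed_grid")
  P <- structure(list(prob = p, grid = g, bandwidth = 1, sample_id = "P"),
                 class = "density_grid")
  Q <- structure(list(prob = q, grid = g, bandwidth = 1, sample_id = "Q"),
                 class = "density_grid")
  list(P = P, Q = Q)
}
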