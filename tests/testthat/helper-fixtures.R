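# Small fixtures built in code.

toy_metadata <- function(ids, ph = NULL, habitat = "fertile grassland") {
  data.frame(sample_id = ids,
             pH = ph %||% seq(4, 8, length.out = length(ids)),
             habitat = rep_len(habitat, length(ids)),
             stringsAsFactors = FALSE)
}

toy_table <- function(counts, ph = NULL, habitat = "fertile grassland") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("OTU%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
  otu_table(counts, toy_metadata(colnames(counts), ph, habitat))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Simulate one OTU's counts from a known HOF truth over a fixed gradient.
sim_counts <- function(type, params, M, n = 300, seed = 1,
                       rng = c(3.63, 8.75), rev = FALSE) {
  set.seed(seed)
  ph <- runif(n, rng[1], rng[2])
  x <- scale_gradient(ph, rng[1], rng[2])
  if (rev) x <- 1 - x
  mu <- hof_response(x, type, params, M)
  list(ph = ph, mu = mu, counts = rpois(n, mu))
}

write_tsv_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
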