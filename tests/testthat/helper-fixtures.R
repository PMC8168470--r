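# small in-code builders shared across test files

# a contrast with explicit statuses; p/log2fc chosen to match the status
toy_contrast <- function(genes_up = character(0), genes_down = character(0),
                         genes_ns = character(0), id = "TOY") {
  gene <- c(genes_up, genes_down, genes_ns)
  lfc <- c(rep(2, length(genes_up)), rep(-2, length(genes_down)),
           rep(0, length(genes_ns)))
  p <- c(rep(1e-4, length(genes_up) + length(genes_down)),
         rep(0.5, length(genes_ns)))
  contrast_from_stats(gene, lfc, p, dataset_id = id)
}

# random status contrast over a shared universe (for property tests)
random_contrast <- function(universe, id = "RND") {
  status <- sample(c("up", "down", "ns"), length(universe), replace = TRUE,
                   prob = c(0.2, 0.2, 0.6))
  lfc <- ifelse(status == "up", 2, ifelse(status == "down", -2, 0))
  p <- ifelse(status == "ns", 0.5, 1e-4)
  contrast_from_stats(universe, lfc, p, dataset_id = id)
}

# tiny array dataset with a known shift on selected genes
toy_dataset <- function(n_genes = 50, shift_genes = character(0), shift = 2,
                        noise_sd = 0.1, n = 4, seed = 42, id = "TOYDS") {
  withr::with_seed(seed, {
    genes <- sprintf("T%03d", seq_len(n_genes))
    base <- rnorm(n_genes, 7, 1)
    vals <- base + matrix(rnorm(n_genes * 2 * n, 0, noise_sd), n_genes, 2 * n)
    rownames(vals) <- genes
    vals[match(shift_genes, genes), seq_len(n)] <-
      vals[match(shift_genes, genes), seq_len(n), drop = FALSE] + shift
  })
  treg_dataset(vals, rep(c("case", "control"), each = n), id, platform = "array")
}

gmt_tempfile <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
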