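# Small programmatic fixtures shared across test files.

# a tiny survey table: 2 plots, 2 species, 2 years, up to 3 rounds
tiny_surveys <- function() {
  data.frame(
    plot_id = c("A", "A", "A", "B", "B", "A", "B"),
    region  = "R1",
    year    = c(2008L, 2008L, 2008L, 2008L, 2008L, 2009L, 2009L),
    round   = c(1L, 2L, 3L, 1L, 2L, 1L, 1L),
    species = c("s1", "s1", "s2", "s1", "s3", "s2", "s3"),
    count   = c(1L, 3L, 2L, 1L, 2L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

tiny_meta <- function() {
  data.frame(
    plot_id = c("A", "B", "C"),
    region = "R1",
    x = c(0, 3000, 0),
    y = c(0, 4000, 1000),
    intensity = c(1, 2, 3),
    stringsAsFactors = FALSE
  )
}

# random survey table over given dimensions (presence rate pr)
random_surveys <- function(n_plots = 4, n_species = 5, n_years = 2,
                           n_rounds = 3, pr = 0.4) {
  grid <- expand.grid(
    plot_id = sprintf("P%02d", seq_len(n_plots)),
    year = 2007L + seq_len(n_years),
    round = seq_len(n_rounds),
    species = sprintf("s%02d", seq_len(n_species)),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$region <- "R1"
  grid$count <- stats::rpois(nrow(grid), 0.8) * stats::rbinom(nrow(grid), 1, pr)
  grid[grid$count > 0, c("plot_id", "region", "year", "round", "species",
                         "count")]
}

# incidence community matrix from a plain 0/1 matrix
inc_matrix <- function(m, scope = "y1") {
  community_matrix(m, scope = scope, type = "incidence")
}

# write a data.frame to a temp CSV, return the path
tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}
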