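# Shared fixtures, built once per test run.

# tiny GRanges peak constructor from 0-based coordinates
mk_peaks <- function(chrom, start, end, summit = NULL, score = NULL,
                     name = NULL) {
  gr <- genomic_interval(chrom, start, end)
  gr$name <- if (is.null(name)) paste0("p", seq_along(gr)) else name
  gr$score <- if (is.null(score)) rep(1, length(gr)) else score
  gr$summit <- as.integer(if (is.null(summit)) (start + end) %/% 2 else summit)
  gr
}

# coverage track from 0-based bedGraph-style tuples
mk_track <- function(chrom, start, end, count, total) {
  gr <- genomic_interval(chrom, start, end)
  gr$score <- count
  coverage_track(gr, total)
}

# one default synthetic scenario + pipeline run, cached across test files
scenario_cache <- new.env(parent = emptyenv())

default_scenario <- function() {
  if (is.null(scenario_cache$sc)) {
    dir <- file.path(tempdir(), "secistrome_default_scenario")
    unlink(dir, recursive = TRUE)
    scenario_cache$sc <- generate_scenario(scenario_params(seed = 1), dir = dir)
  }
  scenario_cache$sc
}

default_pipeline <- function() {
  if (is.null(scenario_cache$run)) {
    sc <- default_scenario()
    out <- file.path(tempdir(), "secistrome_default_run")
    unlink(out, recursive = TRUE)
    scenario_cache$run <- run_pipeline(sc$paths$config, out)
  }
  scenario_cache$run
}
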