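# Shared fixtures built in code.

random_distribution <- function() {
  x <- stats::runif(4)
  x / sum(x)
}

# A distribution with no category-1 mass, as at enrollment.
random_enrollment <- function() {
  x <- c(0, stats::runif(3))
  x / sum(x)
}

base_run <- local({
  cache <- list()
  function(disease) {
    if (is.null(cache[[disease]])) {
      cache[[disease]] <<- run_model(default_parameters(disease))
    }
    cache[[disease]]
  }
})
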