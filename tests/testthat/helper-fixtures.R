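# One shared default fixture per test run (simulation is the expensive step)
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, spec) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, simulate_fixture(spec), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_fixture <- function() {
  cached_fixture("default", fixture_spec(seed = 101))
}

# pipeline through counting and RPKM, memoized alongside the fixture
default_rpkm <- function() {
  if (!exists("default_rpkm_tbl", envir = .fixture_cache)) {
    fx <- default_fixture()
    counts <- count_reads(fx$alignments, fx$annotation)
    assign("default_rpkm_tbl", compute_rpkm(counts, fx$annotation),
           envir = .fixture_cache)
  }
  get("default_rpkm_tbl", envir = .fixture_cache)
}
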