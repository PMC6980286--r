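# Shared fixtures, memoised across test files (expensive objects such as
# the full ETK library and its learned dictionary are built once per
# session, on first use).

.tk_test_cache <- new.env(parent = emptyenv())

tk_cache <- function(name, expr) {
  if (!exists(name, envir = .tk_test_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .tk_test_cache)
  }
  get(name, envir = .tk_test_cache, inherits = FALSE)
}

default_grid <- function() tk_cache("grid", time_grid())
default_aif <- function() tk_cache("aif", parker_aif(default_grid()))

# boxcar plasma input (Cp = 1 mM over the whole window) for closed forms
boxcar_aif <- function(grid = default_grid()) {
  aif_curve(grid, cp = rep(1, grid$n_frames), hct = 0.4)
}

patlak_library <- function() {
  tk_cache("patlak_lib", build_library("patlak", aif = default_aif()))
}

patlak_dictionary <- function() {
  tk_cache("patlak_dict",
           ksvd_learn(patlak_library(), r = 100L, q = 2L, n_iters = 10L,
                      seed = 1L)$dictionary)
}

etk_library_full <- function() {
  tk_cache("etk_lib", build_library("etk", aif = default_aif()))
}

# dictionary trained on the 2x-strided grid subsample (desk-scale training,
# errors always evaluated on the full library)
etk_dictionary <- function() {
  tk_cache("etk_dict", {
    sg <- tkdce:::stride_grid(default_param_grid("etk"), 2L)
    lib <- build_library("etk", sg, default_aif())
    ksvd_learn(lib, r = 100L, q = 3L, n_iters = 30L, seed = 1L)$dictionary
  })
}
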