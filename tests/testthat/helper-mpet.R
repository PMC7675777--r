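# shared lazily-built fixtures (expensive objects computed once per session)

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# the default study configuration: 2D annulus, reference parameters,
# pulsatile inflow, dt = 0.1 s, up to 50 cycles
default_run <- function() {
  memo("default_run", function() {
    params <- mpet_params()
    mesh <- make_shell(resolution = 6)
    wf <- synth_waveform(mean_flow = 1.25e-5, pulsatility = 0.4,
                         period = 1.0, n_samples = 101)
    pb <- mpet_problem(mesh, params, waveform = wf, dt = 0.1)
    run_cycles(pb, n_cycles = 50, tol = 1e-4, record_flux = TRUE)
  })
}

terzaghi_bench <- function() {
  memo("terzaghi_bench", function() terzaghi_benchmark(n_elements = c(64, 128, 256)))
}

mms_result <- function() {
  memo("mms_result", function() mms_study())
}

coarse_annulus <- function() memo("coarse_annulus", function() make_shell(resolution = 3))

expect_no_violations <- function(report) {
  expect_equal(nrow(report), 0, info = paste(report$message, collapse = "; "))
}
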