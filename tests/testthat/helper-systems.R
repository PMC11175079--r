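# Shared fixtures, built once per test run and cached. Meshes are kept
# small here; the acceptance tests build their own full-size systems.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

small_forward <- function() {
  fixture("small_forward", function() {
    el <- electrode_array(16)
    pr <- adjacent_protocol(el, current = 5e-3)
    mesh <- disk_mesh(0.2, n_rings = 8, sigma = 0.17)
    list(el = el, pr = pr, mesh = mesh,
         u0 = solve_forward(mesh, el, pr))
  })
}

small_system <- function() {
  fixture("small_system", function() {
    study_system(study_config(n_rings = 10, snr_db = NULL))
  })
}

# deterministic random matrix helper
rmat <- function(n, m, seed, positive = FALSE) {
  set.seed(seed)
  x <- matrix(rnorm(n * m), n, m)
  if (positive) abs(x) + 0.1 else x
}

# lookup helper: row index of (drive electrode, first measurement
# electrode) in a protocol
protocol_row <- function(pr, drive, meas) {
  which(pr$injection_of == drive & pr$measurements[, 1L] == meas)
}

new_frame2 <- function(values, protocol, role = "difference") {
  eitlf:::new_frame(values, protocol, role)
}

# 4-connected component labelling of a logical matrix (flood fill)
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      if (lab[q] != 0L || !mask[q]) next
      lab[q] <- cur
      i <- ((q - 1L) %% nrow(mask)) + 1L
      j <- ((q - 1L) %/% nrow(mask)) + 1L
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          queue <- c(queue, (jj - 1L) * nrow(mask) + ii)
        }
      }
    }
  }
  lab
}
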