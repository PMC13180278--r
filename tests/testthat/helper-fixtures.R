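# Shared, lazily built fixtures.  Everything is generated in code from
# fixed seeds; expensive objects are cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# default-condition spectral phantom (the study conditions)
default_phantom <- function(seed = 7L) {
  fixture(paste0("phantom_", seed),
          function() make_spectral_phantom(phantom_spec(seed = seed)))
}

default_flow_ours <- function(seed = 7L) {
  fixture(paste0("flow_ours_", seed), function() {
    ph <- default_phantom(seed)
    pre <- preprocess_spectra(ph$volume)
    bank <- walsh_window_bank(orders = 1:3, N = dim(pre$data)[4], alpha = 0.08)
    split_spectrum_flow(pre, bank, "isca")
  })
}

# small spectral volume built directly from an array, for unit tests
manual_spectral_volume <- function(data, k_grid = NULL) {
  n_k <- dim(data)[4]
  if (is.null(k_grid)) k_grid <- (seq_len(n_k) - 1) / n_k
  structure(list(data = data, k_grid = k_grid, meta = NULL),
            class = "spectral_volume")
}

manual_complex_volume <- function(data) {
  structure(list(data = data, z_pitch = 1, provenance = "test"),
            class = "complex_volume")
}

# rank-based AUC (Mann-Whitney)
rank_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# recursive flood-fill component sizes, an independent 8-connectivity oracle
flood_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  sizes <- c()
  for (i0 in seq_len(nr)) for (j0 in seq_len(nc)) {
    if (!mask[i0, j0] || seen[i0, j0]) next
    stack <- list(c(i0, j0)); seen[i0, j0] <- TRUE; n <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      n <- n + 1L
      for (di in -1:1) for (dj in -1:1) {
        i <- p[1] + di; j <- p[2] + dj
        if (i >= 1 && i <= nr && j >= 1 && j <= nc &&
            mask[i, j] && !seen[i, j]) {
          seen[i, j] <- TRUE
          stack[[length(stack) + 1]] <- c(i, j)
        }
      }
    }
    sizes <- c(sizes, n)
  }
  sizes
}

# ten-seed en face phantom batch with full quantification (criteria fixtures)
enface_batch <- function() {
  fixture("enface_batch", function() {
    set.seed(99)
    lapply(1:10, function(s) {
      ab <- c(stats::runif(1, 0.26, 0.38), stats::runif(1, 0.20, 0.30))
      rot <- stats::runif(1, 0, pi)
      ph <- make_enface_phantom(n_px = 240L,
                                faz_shape = list(semi_axes_mm = ab,
                                                 rotation = rot),
                                seed = s)
      q <- quantify_angiogram(ph$angiogram)
      list(ph = ph, q = q)
    })
  })
}

# default-condition pipeline run, shared between the enhancement criterion
# and the bundle-writing test; writes its bundle to a session temp dir
default_run7 <- function() {
  fixture("run_seed7", function() {
    out_dir <- file.path(tempdir(), "octawalsh-run7")
    octa_run(octa_config(seed = 7L, out_dir = out_dir),
             phantom = default_phantom(7L))
  })
}
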