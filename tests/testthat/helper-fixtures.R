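# shared fixtures and small configs for the test suite

# fixed-column ATOM record
atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                      occ = 1, alt = " ") {
  sprintf("ATOM  %5d %-4s%s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
          serial, paste0(" ", name), alt, resname, chain, resno, x, y, z,
          occ, 0, substr(name, 1, 1))
}

# backbone ATOM lines for one model: residues at jittered ideal positions
model_lines <- function(resnames, jitter = 0, chain = "A") {
  L <- length(resnames)
  xyz <- build_backbone(rep(-57, L), rep(-47, L))
  xyz <- xyz + jitter
  lines <- character(0)
  s <- 0L
  for (i in seq_len(L)) {
    for (j in 1:3) {
      s <- s + 1L
      p <- xyz[3 * (i - 1) + j, ]
      lines <- c(lines, atom_line(s, c("N", "CA", "C")[j], resnames[i],
                                  chain, i, p[1], p[2], p[3]))
    }
  }
  lines
}

write_toy_pdb <- function(path, resnames = c("ALA", "ALA", "ALA"),
                          n_models = 2, wrap_models = TRUE) {
  lines <- character(0)
  for (m in seq_len(n_models)) {
    body <- model_lines(resnames, jitter = (m - 1) * 0.01)
    if (wrap_models) {
      lines <- c(lines, sprintf("MODEL     %4d", m), body, "ENDMDL")
    } else {
      lines <- c(lines, body)
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# quick regressor settings for unit tests (full-size defaults are far too
# heavy for a toy simulation)
rc_light <- function(seed = 1, n_estimators = 60) {
  regressor_config(learning_rate = 0.1, n_estimators = n_estimators,
                   max_depth = 4, num_leaves = 16, max_bin = 64,
                   feature_fraction = 1, seed = seed)
}

# random rigid-body motion applied to a set of points (rows)
random_rigid <- function(points, seed) {
  withr::with_seed(seed, {
    qr_dec <- qr(matrix(rnorm(9), 3))
    R <- qr.Q(qr_dec)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    t_vec <- rnorm(3, sd = 10)
  })
  sweep(points %*% t(R), 2, -t_vec)
}
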