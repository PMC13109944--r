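# Shared fixtures and independent oracles for the test-suite.
# Oracles deliberately re-derive everything from the printed formulas with
# plain R loops; they never call the package's compiled paths.

m0_table <- function(A = 23, B = 10, cb = 0.4226) {
  interaction_table(list(species_params("M0", A, B, cb)))
}

r_min_m0 <- sqrt(9 / 8) * 0.922

# brute-force energy / forces / stress oracle, O(N^2) + O(N^3), plain
# (non-Lees-Edwards wrap is enough when le = 0)
brute_energy <- function(pos, L, le = 0, A = 23, B = 10, cb = 0.4226,
                         w = 0.3, d2 = 0.922, d3 = 1.1, rc = 2) {
  mi <- function(v) {
    nz <- round(v[3] / L)
    v[3] <- v[3] - nz * L
    v[1] <- v[1] - nz * le
    v[1] <- v[1] - L * round(v[1] / L)
    v[2] <- v[2] - L * round(v[2] / L)
    v
  }
  lam <- function(r) if (r > rc) 0 else (d3 / r)^10 * (1 - (r / rc)^10)^2
  n <- nrow(pos)
  E <- 0
  if (n >= 2)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      r <- sqrt(sum(mi(pos[j, ] - pos[i, ])^2))
      if (r <= rc) E <- E + A * ((d2 / r)^18 - (d2 / r)^16)
    }
  if (n >= 3)
    for (i in 1:n) {
      js <- setdiff(1:n, i)
      for (a in 1:(length(js) - 1)) for (b in (a + 1):length(js)) {
        rij <- mi(pos[js[a], ] - pos[i, ])
        rik <- mi(pos[js[b], ] - pos[i, ])
        r1 <- sqrt(sum(rij^2)); r2 <- sqrt(sum(rik^2))
        if (r1 <= rc && r2 <= rc) {
          cth <- sum(rij * rik) / (r1 * r2)
          E <- E + B * lam(r1) * lam(r2) * exp(-((cth - cb) / w)^2)
        }
      }
    }
  E
}

# random small cluster that has pairs and triplets in range
random_cluster <- function(n = 6, L = 8, seed = 1, spread = 1.6) {
  set.seed(seed)
  center <- matrix(runif(3, 3, 5), n, 3, byrow = TRUE)
  pos <- center + matrix(runif(3 * n, -spread, spread), n, 3)
  pos
}

# deterministic small relaxed gel shared across rheology tests (cached per
# session); medium density so the crossover sits inside the chirp band
rheo_gel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      prot <- prep_protocol(phi = 0.15, t_hot = 20, t_quench = 40,
                            stop_T = 1e-8, seed = 3)
      cache <<- prepare_single_gel(gel_species("PIC"), prot, L = 6)
    }
    cache
  }
})

# bond-percolation oracle: BFS with unwrapped coordinates; a revisit with
# conflicting unwrapped position means the cluster winds around the box
percolates <- function(cfg, bond = 2.0) {
  p <- cfg$positions
  n <- nrow(p)
  L <- cfg$L
  adj <- vector("list", n)
  for (i in 1:(n - 1)) {
    dv <- minimum_image(sweep(p[(i + 1):n, , drop = FALSE], 2, p[i, ]),
                        L, cfg$le_offset)
    js <- which(rowSums(dv^2) < bond^2) + i
    for (j in js) {
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  visited <- rep(FALSE, n)
  for (s in 1:n) {
    if (visited[s]) next
    un <- matrix(NA_real_, n, 3)
    un[s, ] <- p[s, ]
    queue <- s
    visited[s] <- TRUE
    while (length(queue)) {
      i <- queue[1]
      queue <- queue[-1]
      for (j in adj[[i]]) {
        d <- minimum_image(p[j, ] - p[i, ], L, cfg$le_offset)
        cand <- un[i, ] + d
        if (!visited[j]) {
          visited[j] <- TRUE
          un[j, ] <- cand
          queue <- c(queue, j)
        } else if (max(abs(un[j, ] - cand)) > L / 2) return(TRUE)
      }
    }
  }
  FALSE
}

# cross-species contacts per particle (pair distance < cutoff)
cross_contacts <- function(cfg, a, b, cutoff = 1.3) {
  pa <- cfg$positions[cfg$species == a, , drop = FALSE]
  pb <- cfg$positions[cfg$species == b, , drop = FALSE]
  cnt <- 0
  for (i in seq_len(nrow(pa))) {
    dv <- minimum_image(sweep(pb, 2, pa[i, ]), cfg$L, cfg$le_offset)
    cnt <- cnt + sum(rowSums(dv^2) < cutoff^2)
  }
  cnt / (nrow(pa) + nrow(pb))
}
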