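# Discrete model assembly: finite-volume capacities, face conductances,
# upwind advection couplings and boundary transfer coefficients, plus the
# precomputed tridiagonal (Thomas) factors consumed by the C++ stepper.
#
# Conventions: cell-centred grid; G[[a]][i,...] is the conductance (W/K) of
# the face between node i and i+1 along axis a (last index unused = 0);
# blo/bhi[[a]] are boundary transfer coefficients (W/K) on the low/high face
# of axis a, shaped like the face. The boundary heat flux is
# b * (T - T_core): Robin coupling h*A on tissue faces (h = k_eff/d),
# Dirichlet-by-ghost 2*k_b*A/h_cell at vessel inlets, 0 at vessel outlets
# (pure advective outflow) and on the axisymmetric r = 0 face.

harmonic_mean <- function(a, b) 2 * a * b / (a + b)

build_model <- function(fields, config) {
  grid <- fields$grid
  sc <- fields$scenario
  mat <- sc$materials
  dims <- grid$dims
  h <- grid$h
  lumen <- fields$vessel_id > 0L

  rho_c <- array(mat$rho_t * mat$c_pt, dims)
  rho_c[lumen] <- mat$rho_b * mat$c_pb
  k <- array(mat$k_eff, dims)
  k[lumen] <- mat$k_b
  h_rob <- mat$k_eff / sc$d

  if (grid$mode == "axisym") {
    r <- grid_axes(grid)[[1]]
    r_face <- seq_len(dims[1]) * h[1]          # face after node i at r = i*dr
    V <- array(2 * pi * r * h[1] * h[2], dims) # per-cell volume
    A1 <- array(2 * pi * r_face * h[2], dims)  # r-face areas
    A2 <- array(2 * pi * r * h[1], dims)       # z-face areas
    Aface <- list(A1, A2, NULL)
    Abound <- list(lo = list(0 * A1[1, , 1], A2[, 1, 1], NULL),
                   hi = list(rep(2 * pi * grid$size[1] * h[2], dims[2]),
                             A2[, 1, 1], NULL))
  } else {
    V <- array(prod(h), dims)
    Aface <- list(array(h[2] * h[3], dims), array(h[1] * h[3], dims),
                  array(h[1] * h[2], dims))
    Abound <- list(lo = list(matrix(h[2] * h[3], dims[2], dims[3]),
                             matrix(h[1] * h[3], dims[1], dims[3]),
                             matrix(h[1] * h[2], dims[1], dims[2])),
                   hi = NULL)
    Abound$hi <- Abound$lo
  }

  cap <- V * rho_c

  shift_lead <- function(x, a) {
    # x indexed one step ahead along axis a (value at i+1), junk in last slot
    idx <- rep(list(quote(expr = )), 3)
    idx[[a]] <- c(2:dims[a], dims[a])
    array(do.call(`[`, c(list(x), idx, list(drop = FALSE))), dims)
  }

  G <- vector("list", 3)
  for (a in 1:3) {
    if (dims[a] == 1L) next
    kf <- harmonic_mean(k, shift_lead(k, a))
    Ga <- Aface[[a]] * kf / h[a]
    idx <- rep(list(quote(expr = )), 3)
    idx[[a]] <- dims[a]
    Ga <- do.call(`[<-`, c(list(Ga), idx, list(0)))
    G[[a]] <- Ga
  }

  advlo <- advhi <- vector("list", 3)
  wcomp <- list(fields$w1, fields$w2, fields$w3)
  for (a in 1:3) {
    if (is.null(wcomp[[a]]) || dims[a] == 1L) next
    advlo[[a]] <- cap * pmax(wcomp[[a]], 0) / h[a]
    advhi[[a]] <- cap * pmax(-wcomp[[a]], 0) / h[a]
  }

  # boundary transfer coefficients
  face_slice <- function(arr, a, i) {
    idx <- rep(list(quote(expr = )), 3)
    idx[[a]] <- i
    drop(do.call(`[`, c(list(arr), idx)))
  }
  blo <- bhi <- vector("list", 3)
  for (a in 1:3) {
    if (dims[a] == 1L) next
    blo[[a]] <- h_rob * Abound$lo[[a]]
    bhi[[a]] <- h_rob * Abound$hi[[a]]
    if (grid$mode == "axisym" && a == 1L) blo[[a]][] <- 0  # symmetry axis
    # vessel inlet (Dirichlet at T_core) / outlet (zero diffusive flux)
    vid_lo <- face_slice(fields$vessel_id, a, 1L)
    vid_hi <- face_slice(fields$vessel_id, a, dims[a])
    for (kv in seq_along(sc$vessels)) {
      v <- sc$vessels[[kv]]
      fa <- v$flow_sign * v$direction[a]
      if (abs(fa) < 1e-9) next
      idv <- if (grid$mode == "axisym") 1L else kv
      A_lo <- face_slice(Aface[[a]], a, 1L)
      dirich <- 2 * mat$k_b * A_lo / h[a]
      if (fa > 0) {           # inflow at low face, outflow at high face
        blo[[a]][vid_lo == idv] <- dirich[vid_lo == idv]
        bhi[[a]][vid_hi == idv] <- 0
      } else {
        bhi[[a]][vid_hi == idv] <- dirich[vid_hi == idv]
        blo[[a]][vid_lo == idv] <- 0
      }
    }
  }

  list(dims = dims, h = h, mode = grid$mode, cap = cap, V = V,
       rho_c = rho_c, G = G, advlo = advlo, advhi = advhi,
       blo = blo, bhi = bhi, T_core = mat$T_core)
}

# Precompute the signed Thomas factors for each axis at a fixed dt.
build_factors <- function(model, dt) {
  dims <- model$dims
  Tc <- model$T_core
  axes <- vector("list", 3)
  for (a in 1:3) {
    if (dims[a] == 1L || is.null(model$G[[a]])) next
    perm <- c(a, setdiff(1:3, a))
    m <- dims[a]
    q <- prod(dims[-a])
    capP <- matrix(aperm(model$cap, perm), m, q)
    GP <- matrix(aperm(model$G[[a]], perm), m, q)
    alo <- if (is.null(model$advlo[[a]])) 0 * capP else
      matrix(aperm(model$advlo[[a]], perm), m, q)
    ahi <- if (is.null(model$advhi[[a]])) 0 * capP else
      matrix(aperm(model$advhi[[a]], perm), m, q)
    Gm1 <- rbind(0, GP[-m, , drop = FALSE])   # conductance to node i-1
    Gp <- GP
    Gp[m, ] <- 0
    dg <- capP / dt + Gm1 + Gp + alo + ahi
    dg[1, ] <- dg[1, ] + as.numeric(model$blo[[a]])
    dg[m, ] <- dg[m, ] + as.numeric(model$bhi[[a]])
    csub <- Gm1 + alo
    csub[1, ] <- 0
    csup <- Gp + ahi
    csup[m, ] <- 0
    radd <- 0 * dg
    radd[1, ] <- (as.numeric(model$blo[[a]]) + alo[1, ]) * Tc
    radd[m, ] <- radd[m, ] + (as.numeric(model$bhi[[a]]) + ahi[m, ]) * Tc
    asub <- -csub
    cc <- -csup
    cp <- inv <- 0 * dg
    inv[1, ] <- 1 / dg[1, ]
    cp[1, ] <- cc[1, ] * inv[1, ]
    for (i in seq_len(m)[-1]) {
      inv[i, ] <- 1 / (dg[i, ] - asub[i, ] * cp[i - 1, ])
      cp[i, ] <- cc[i, ] * inv[i, ]
    }
    back <- function(x) aperm(array(x, dims[perm]), order(perm))
    axes[[a]] <- list(asub = back(asub), cp = back(cp), inv = back(inv),
                      radd = back(radd))
  }
  list(dims = as.integer(dims), rcap = model$cap / dt, axes = axes,
       dt = dt, T_core = Tc)
}

# One implicit step with full energy bookkeeping, in plain R. Returns the
# post-step field plus the per-step energy ledger: storage change, boundary
# (Robin/Dirichlet) losses and net advective outflow per sweep, and the
# source input. The finite-volume sweeps are conservative, so
# dE == E_source + Q_boundary + Q_advection to round-off; tests assert this.
bh_step_energy <- function(model, fac, T_arr, src_dT = NULL) {
  dims <- model$dims
  dt <- fac$dt
  Tc <- model$T_core
  shift <- function(x, a, by, fill = NA) {
    idx <- rep(list(quote(expr = )), 3)
    m <- dims[a]
    e <- rep(list(quote(expr = )), 3)
    if (by == 1L) idx[[a]] <- c(2:m, m) else idx[[a]] <- c(1L, 1:(m - 1))
    out <- array(do.call(`[`, c(list(x), idx, list(drop = FALSE))), dims)
    e[[a]] <- if (by == 1L) m else 1L
    do.call(`[<-`, c(list(out), e, list(fill)))
  }
  edge <- function(a, end) {
    e <- array(FALSE, dims)
    idx <- rep(list(quote(expr = )), 3)
    idx[[a]] <- if (end == "lo") 1L else dims[a]
    do.call(`[<-`, c(list(e), idx, list(TRUE)))
  }
  Q_bound <- Q_adv <- 0
  E0 <- sum(model$cap * T_arr)
  if (!is.null(src_dT)) T_arr <- T_arr + src_dT / 2
  for (a in 1:3) {
    if (is.null(fac$axes[[a]])) next
    fac1 <- fac
    fac1$axes[setdiff(1:3, a)] <- list(NULL, NULL)
    Ts <- bh_step_r(T_arr, fac1)
    lo <- edge(a, "lo")
    hi <- edge(a, "hi")
    bl <- array(0, dims); bl[lo] <- as.numeric(model$blo[[a]])
    bh <- array(0, dims); bh[hi] <- as.numeric(model$bhi[[a]])
    Q_bound <- Q_bound + dt * sum((bl + bh) * (Tc - Ts))
    if (!is.null(model$advlo[[a]])) {
      ghost_lo <- shift(Ts, a, -1L, fill = Tc)
      ghost_hi <- shift(Ts, a, 1L, fill = Tc)
      Q_adv <- Q_adv + dt * sum(model$advlo[[a]] * (ghost_lo - Ts) +
                                  model$advhi[[a]] * (ghost_hi - Ts))
    }
    T_arr <- Ts
  }
  if (!is.null(src_dT)) T_arr <- T_arr + src_dT / 2
  E_src <- if (is.null(src_dT)) 0 else sum(model$cap * src_dT)
  list(T = T_arr, dE = sum(model$cap * T_arr) - E0, E_src = E_src,
       Q_bound = Q_bound, Q_adv = Q_adv)
}

# Reference implicit step in plain R (same factors as the C++ stepper).
# Used for cross-checking the compiled sweeps and for flux bookkeeping in
# tests; not a production path.
bh_step_r <- function(T_arr, fac) {
  dims <- fac$dims
  for (a in 1:3) {
    ax <- fac$axes[[a]]
    if (is.null(ax)) next
    perm <- c(a, setdiff(1:3, a))
    m <- dims[a]
    q <- prod(dims[-a])
    tP <- matrix(aperm(T_arr, perm), m, q)
    rcapP <- matrix(aperm(fac$rcap, perm), m, q)
    asub <- matrix(aperm(ax$asub, perm), m, q)
    cp <- matrix(aperm(ax$cp, perm), m, q)
    inv <- matrix(aperm(ax$inv, perm), m, q)
    radd <- matrix(aperm(ax$radd, perm), m, q)
    d <- 0 * tP
    d[1, ] <- (rcapP[1, ] * tP[1, ] + radd[1, ]) * inv[1, ]
    for (i in seq_len(m)[-1])
      d[i, ] <- (rcapP[i, ] * tP[i, ] + radd[i, ] - asub[i, ] * d[i - 1, ]) *
        inv[i, ]
    x <- d
    for (i in rev(seq_len(m - 1)))
      x[i, ] <- d[i, ] - cp[i, ] * x[i + 1, ]
    T_arr <- aperm(array(x, dims[perm]), order(perm))
  }
  T_arr
}
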