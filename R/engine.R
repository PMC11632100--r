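# Reverse-mode (adjoint) differentiation engine for optical chains.
#
# Every differentiable forward pass records a tape of primitive operations on
# complex rasters. Each record knows how to pull a cotangent back through
# itself and how to deposit gradients on the named scalar/raster parameters
# it consumed. For a real-valued loss L and a complex intermediate v we carry
# the Wirtinger cotangent g = dL/d conj(v); for a real parameter p entering
# through v the chain rule is dL/dp = 2 Re( sum( Conj(g) * dv/dp ) ).
#
# Primitives: leaf, add, scale (complex scalar with parameter derivatives),
# mulmat (pointwise constant matrix), phase (SLM pixel rasters), prop
# (Rayleigh-Sommerfeld hop, differentiable in z via the analytic kernel
# derivative), linop (any linear map given with its adjoint, used for the
# Richards-Wolf focusing and zoomed propagation).

tape_new <- function() {
  e <- new.env(parent = emptyenv())
  e$vals <- list()
  e$recs <- list()
  e$n <- 0L
  e
}

tp_push <- function(tape, val, ins = integer(0), back = NULL) {
  tape$n <- tape$n + 1L
  id <- tape$n
  tape$vals[[id]] <- val
  tape$recs[[id]] <- list(ins = ins, back = back)
  id
}

tp_val <- function(tape, id) tape$vals[[id]]

tp_leaf <- function(tape, val) tp_push(tape, val)

tp_add <- function(tape, ids) {
  ids <- ids[!vapply(ids, is.null, logical(1))]
  ids <- as.integer(unlist(ids))
  if (length(ids) == 1L) return(ids)
  val <- Reduce(`+`, lapply(ids, function(i) tape$vals[[i]]))
  tp_push(tape, val, ins = ids,
          back = function(g, tape) list(ins = rep(list(g), length(ids)), pgrad = NULL))
}

# out = cf * v; dparams: named list of dcf/dparam (complex scalars)
tp_scale <- function(tape, id, cf, dparams = NULL) {
  force(id); force(cf); force(dparams)
  vin <- tape$vals[[id]]
  val <- cf * vin
  tp_push(tape, val, ins = id, back = function(g, tape) {
    pg <- NULL
    if (!is.null(dparams)) {
      pg <- lapply(dparams, function(d) 2 * sum(Re(Conj(g) * (d * vin))))
    }
    list(ins = list(Conj(cf) * g), pgrad = pg)
  })
}

# out = M * v pointwise, M constant
tp_mulmat <- function(tape, id, M) {
  force(id); force(M)
  val <- M * tape$vals[[id]]
  tp_push(tape, val, ins = id, back = function(g, tape) {
    list(ins = list(Conj(M) * g), pgrad = NULL)
  })
}

# out = v * tr with tr = exp(1i * phase) (or a precomputed complex
# transmission, e.g. including a noise model); if pname is given, the phase
# raster is an optimizable parameter family and receives the per-pixel
# gradient 2 Re(Conj(g) * 1i * out). When tr includes a misalignment
# resampling of the mask this gradient is the zero-shift approximation;
# discovery runs are noiseless, so the exact case is the one optimized.
tp_phase <- function(tape, id, phase = NULL, pname = NULL, tr = NULL) {
  force(id); force(pname)
  if (is.null(tr)) tr <- exp(1i * phase)
  val <- tr * tape$vals[[id]]
  out_id <- tp_push(tape, val, ins = id, back = function(g, tape) {
    pg <- NULL
    if (!is.null(pname)) {
      pg <- stats::setNames(list(2 * Re(Conj(g) * (1i * val))), pname)
    }
    list(ins = list(Conj(tr) * g), pgrad = pg)
  })
  out_id
}

# Rayleigh-Sommerfeld hop on the field's own grid; differentiable in z when
# zname is given. prep may be shared across the components of one hop.
tp_prop <- function(tape, id, prep, zname = NULL) {
  force(id); force(prep); force(zname)
  ufft <- stats::fft(rs_pad(tape$vals[[id]], prep))
  val <- rs_crop(fft2(ufft * prep$H[["z"]], inverse = TRUE), prep)
  tp_push(tape, val, ins = id, back = function(g, tape) {
    gin <- rs_apply(NULL, prep, "z", conjugate = TRUE,
                    ufft = stats::fft(rs_pad(g, prep)))
    pg <- NULL
    if (!is.null(zname)) {
      dval <- rs_crop(fft2(ufft * prep$H[["dz"]], inverse = TRUE), prep)
      pg <- stats::setNames(list(2 * sum(Re(Conj(g) * dval))), zname)
    }
    list(ins = list(gin), pgrad = pg)
  })
}

# generic linear operator with explicit adjoint; optionally differentiable in
# one scalar parameter through dval (the derivative of the output value)
tp_linop <- function(tape, ids, val, adjoint, pname = NULL, dval = NULL) {
  force(adjoint); force(pname); force(dval)
  ids <- as.integer(ids)
  tp_push(tape, val, ins = ids, back = function(g, tape) {
    pg <- NULL
    if (!is.null(pname))
      pg <- stats::setNames(list(2 * sum(Re(Conj(g) * dval))), pname)
    list(ins = adjoint(g), pgrad = pg)
  })
}

# zoomed RS hop onto an output window (used at detector objectives)
tp_czt_prop <- function(tape, id, prep, window, zname = NULL) {
  force(id)
  ufft <- stats::fft(rs_pad(tape$vals[[id]], prep))
  V <- if (prep$z == 0) ufft else ufft * prep$H[["z"]]
  val <- czt_evaluate(V, prep, window)
  dval <- if (!is.null(zname)) czt_evaluate(ufft * prep$H[["dz"]], prep, window) else NULL
  adjoint <- function(g) {
    gV <- czt_evaluate_adjoint(g, prep, window)
    if (prep$z != 0) gV <- gV * Conj(prep$H[["z"]])
    list(rs_crop(stats::fft(gV, inverse = TRUE), prep))
  }
  tp_linop(tape, id, val, adjoint, pname = zname, dval = dval)
}

# Richards-Wolf focusing of a transverse tracked field; returns the three
# focal component ids
tp_focus <- function(tape, exid, eyid, fp, window) {
  force(exid); force(eyid)
  ex <- tape$vals[[exid]]; ey <- tape$vals[[eyid]]
  a <- focus_strength(ex, ey, fp)
  w <- fp$apod / pmax(fp$cos_t, 1e-12)
  # real pointwise coefficient matrices of the strength map
  cxx <- w * (fp$cos_t * fp$cos_p^2 + fp$sin_p^2)
  cxy <- w * (fp$cos_t * fp$cos_p * fp$sin_p - fp$sin_p * fp$cos_p)
  cyx <- cxy
  cyy <- w * (fp$cos_t * fp$sin_p^2 + fp$cos_p^2)
  czx <- w * fp$sin_t * fp$cos_p
  czy <- w * fp$sin_t * fp$sin_p
  mk <- function(aval, cx, cy) {
    tp_linop(tape, c(exid, eyid),
             focus_transform(aval, fp, window),
             adjoint = function(g) {
               ga <- focus_transform_adjoint(g, fp, window)
               list(cx * ga, cy * ga)
             })
  }
  list(ex = mk(a$ax, cxx, cxy),
       ey = mk(a$ay, cyx, cyy),
       ez = mk(a$az, czx, czy))
}

# wave plate on a tracked transverse pair; eta/theta optionally parameters
tp_jones <- function(tape, exid, eyid, eta, theta,
                     eta_name = NULL, theta_name = NULL) {
  force(exid); force(eyid)
  J <- wave_plate_jones(eta, theta)
  dJe <- wave_plate_jones_deta(eta, theta)
  dJt <- wave_plate_jones_dtheta(eta, theta)
  row <- function(i) {
    dparams1 <- dparams2 <- list()
    if (!is.null(eta_name)) { dparams1[[eta_name]] <- dJe[i, 1]; dparams2[[eta_name]] <- dJe[i, 2] }
    if (!is.null(theta_name)) { dparams1[[theta_name]] <- dJt[i, 1]; dparams2[[theta_name]] <- dJt[i, 2] }
    if (length(dparams1) == 0L) dparams1 <- dparams2 <- NULL
    tp_add(tape, c(tp_scale(tape, exid, J[i, 1], dparams1),
                   tp_scale(tape, eyid, J[i, 2], dparams2)))
  }
  list(ex = row(1), ey = row(2))
}

# tunable lossless beam splitter on tracked pairs; a and b are lists
# (ex, ey ids) or NULL for a dark port; t in (0, 1) the transmittance
tp_bs <- function(tape, a, b, t, tname = NULL) {
  force(a); force(b); force(tname)
  tcl <- min(max(t, 1e-9), 1 - 1e-9)
  ct <- sqrt(tcl); cr <- 1i * sqrt(1 - tcl)
  dct <- 1 / (2 * sqrt(tcl)); dcr <- -1i / (2 * sqrt(1 - tcl))
  mix <- function(ida, idb, ca, cb, dca, dcb) {
    parts <- list()
    if (!is.null(ida))
      parts <- c(parts, tp_scale(tape, ida, ca,
                                 if (!is.null(tname)) stats::setNames(list(dca), tname)))
    if (!is.null(idb))
      parts <- c(parts, tp_scale(tape, idb, cb,
                                 if (!is.null(tname)) stats::setNames(list(dcb), tname)))
    if (length(parts) == 0L) return(NULL)
    tp_add(tape, parts)
  }
  comp <- function(which) {
    ida <- if (!is.null(a)) a[[which]] else NULL
    idb <- if (!is.null(b)) b[[which]] else NULL
    list(
      c = mix(ida, idb, ct, cr, dct, dcr),
      d = mix(ida, idb, cr, ct, dcr, dct)
    )
  }
  ex <- comp("ex"); ey <- comp("ey")
  list(c = if (is.null(ex$c)) NULL else list(ex = ex$c, ey = ey$c),
       d = if (is.null(ex$d)) NULL else list(ex = ex$d, ey = ey$d))
}

# Run the reverse pass. seeds: list of list(id = node id, g = cotangent).
# Returns the named list of accumulated parameter gradients.
tape_backward <- function(tape, seeds) {
  gs <- vector("list", tape$n)
  for (s in seeds) {
    id <- s$id
    gs[[id]] <- if (is.null(gs[[id]])) s$g else gs[[id]] + s$g
  }
  pgrad <- list()
  for (id in rev(seq_len(tape$n))) {
    g <- gs[[id]]
    if (is.null(g)) next
    rec <- tape$recs[[id]]
    if (is.null(rec$back)) next
    out <- rec$back(g, tape)
    if (!is.null(out$pgrad)) {
      for (nm in names(out$pgrad)) {
        pgrad[[nm]] <- if (is.null(pgrad[[nm]])) out$pgrad[[nm]]
                       else pgrad[[nm]] + out$pgrad[[nm]]
      }
    }
    ins <- rec$ins
    for (j in seq_along(ins)) {
      gi <- out$ins[[j]]
      if (is.null(gi)) next
      i <- ins[j]
      gs[[i]] <- if (is.null(gs[[i]])) gi else gs[[i]] + gi
    }
    gs[[id]] <- NULL   # free
  }
  pgrad
}

# seed helper: cotangents of the components of a tracked field for a loss
# with known gradient w = dL/dI on its intensity raster
intensity_seeds <- function(tape, ids, w) {
  seeds <- list()
  for (id in ids) {
    if (is.null(id)) next
    seeds[[length(seeds) + 1L]] <- list(id = id, g = w * tape$vals[[id]])
  }
  seeds
}
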