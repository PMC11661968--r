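# Independent scalar reference implementation of the standard CFFDRS
# equations (Van Wagner & Pickett 1985), written as a direct per-day
# transliteration of the published program steps (scalar if/else control
# flow, moisture-content intermediates). Used as the cross-check oracle for
# the package's vectorized engine; kept deliberately separate from R/.

oracle_ffmc <- function(ffmc0, t, rh, ws, prec) {
  mo <- 147.2 * (101 - ffmc0) / (59.5 + ffmc0)
  if (prec > 0.5) {
    rf <- prec - 0.5
    if (mo <= 150) {
      mo <- mo + 42.5 * rf * exp(-100 / (251 - mo)) * (1 - exp(-6.93 / rf))
    } else {
      mo <- mo + 42.5 * rf * exp(-100 / (251 - mo)) * (1 - exp(-6.93 / rf)) +
        0.0015 * (mo - 150)^2 * sqrt(rf)
    }
    if (mo > 250) mo <- 250
  }
  ed <- 0.942 * rh^0.679 + 11 * exp((rh - 100) / 10) +
    0.18 * (21.1 - t) * (1 - exp(-0.115 * rh))
  if (mo > ed) {
    ko <- 0.424 * (1 - (rh / 100)^1.7) + 0.0694 * sqrt(ws) * (1 - (rh / 100)^8)
    kd <- ko * 0.581 * exp(0.0365 * t)
    m <- ed + (mo - ed) * 10^(-kd)
  } else {
    ew <- 0.618 * rh^0.753 + 10 * exp((rh - 100) / 10) +
      0.18 * (21.1 - t) * (1 - exp(-0.115 * rh))
    if (mo < ed && mo < ew) {
      kl <- 0.424 * (1 - ((100 - rh) / 100)^1.7) +
        0.0694 * sqrt(ws) * (1 - ((100 - rh) / 100)^8)
      kw <- kl * 0.581 * exp(0.0365 * t)
      m <- ew - (ew - mo) * 10^(-kw)
    } else {
      m <- mo
    }
  }
  ffmc <- 59.5 * (250 - m) / (147.2 + m)
  if (ffmc > 101) ffmc <- 101
  if (ffmc < 0) ffmc <- 0
  ffmc
}

.oracle_el <- c(6.5, 7.5, 9.0, 12.8, 13.9, 13.9, 12.4, 10.9, 9.4, 8.0, 7.0, 6.0)
.oracle_fl <- c(-1.6, -1.6, -1.6, 0.9, 3.8, 5.8, 6.4, 5.0, 2.4, 0.4, -1.6, -1.6)

oracle_dmc <- function(dmc0, t, rh, prec, month) {
  if (prec > 1.5) {
    re <- 0.92 * prec - 1.27
    mo <- 20 + 280 / exp(0.023 * dmc0)
    if (dmc0 <= 33) {
      b <- 100 / (0.5 + 0.3 * dmc0)
    } else if (dmc0 <= 65) {
      b <- 14 - 1.3 * log(dmc0)
    } else {
      b <- 6.2 * log(dmc0) - 17.2
    }
    mr <- mo + 1000 * re / (48.77 + b * re)
    pr <- 244.72 - 43.43 * log(mr - 20)
    if (pr < 0) pr <- 0
  } else {
    pr <- dmc0
  }
  if (t > -1.1) {
    k <- 1.894 * (t + 1.1) * (100 - rh) * .oracle_el[month] * 1e-6
  } else {
    k <- 0
  }
  pr + 100 * k
}

oracle_dc <- function(dc0, t, prec, month) {
  if (prec > 2.8) {
    rd <- 0.83 * prec - 1.27
    qo <- 800 * exp(-dc0 / 400)
    qr <- qo + 3.937 * rd
    dr <- 400 * log(800 / qr)
    if (dr < 0) dr <- 0
  } else {
    dr <- dc0
  }
  if (t > -2.8) {
    v <- 0.36 * (t + 2.8) + .oracle_fl[month]
  } else {
    v <- .oracle_fl[month]
  }
  if (v < 0) v <- 0
  dr + v / 2
}

oracle_isi <- function(ffmc, ws) {
  m <- 147.2 * (101 - ffmc) / (59.5 + ffmc)
  ff <- 91.9 * exp(-0.1386 * m) * (1 + m^5.31 / 49300000)
  0.208 * exp(0.05039 * ws) * ff
}

oracle_bui <- function(dmc, dc) {
  if (dmc == 0 && dc == 0) return(0)
  if (dmc <= 0.4 * dc) {
    u <- 0.8 * dmc * dc / (dmc + 0.4 * dc)
  } else {
    u <- dmc - (1 - 0.8 * dc / (dmc + 0.4 * dc)) * (0.92 + (0.0114 * dmc)^1.7)
  }
  max(u, 0)
}

oracle_fwi <- function(isi, bui) {
  if (bui <= 80) {
    fd <- 0.626 * bui^0.809 + 2
  } else {
    fd <- 1000 / (25 + 108.64 * exp(-0.023 * bui))
  }
  b <- 0.1 * isi * fd
  if (b <= 1) b else exp(2.72 * (0.434 * log(b))^0.647)
}

oracle_dsr <- function(fwi) 0.0272 * fwi^1.77

# step-by-step series oracle: returns a data.frame of daily values
oracle_fwi_series <- function(wx, ffmc0 = 85, dmc0 = 6, dc0 = 15) {
  n <- nrow(wx)
  out <- data.frame(ffmc = numeric(n), dmc = numeric(n), dc = numeric(n),
                    isi = numeric(n), bui = numeric(n), fwi = numeric(n),
                    dsr = numeric(n))
  for (i in seq_len(n)) {
    ffmc0 <- oracle_ffmc(ffmc0, wx$tmax[i], wx$rhmin[i], wx$wind[i], wx$precip[i])
    dmc0 <- oracle_dmc(dmc0, wx$tmax[i], wx$rhmin[i], wx$precip[i], wx$month[i])
    dc0 <- oracle_dc(dc0, wx$tmax[i], wx$precip[i], wx$month[i])
    isi <- oracle_isi(ffmc0, wx$wind[i])
    bui <- oracle_bui(dmc0, dc0)
    fwi <- oracle_fwi(isi, bui)
    out[i, ] <- c(ffmc0, dmc0, dc0, isi, bui, fwi, oracle_dsr(fwi))
  }
  out
}

# random daily weather series for property tests
random_weather <- function(n_days, seed) {
  set.seed(seed)
  data.frame(
    tmax = runif(n_days, -5, 35),
    rhmin = runif(n_days, 5, 100),
    wind = runif(n_days, 0, 50),
    precip = ifelse(runif(n_days) < 0.3, rexp(n_days, 1 / 4), 0),
    month = sample(1:12, 1)
  )
}
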