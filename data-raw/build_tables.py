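#!/usr/bin/env python
"""Build the bundled photon mass-coefficient table.

mu/rho (total attenuation): log-log interpolation through per-element
anchors transcribed from the standard NIST compilations; absorption edges
are anchor pairs just below/above the edge.

mu_en/rho: for C, Al, Cu direct NIST anchors; for N and O anchors solved
from the NIST air and water compound values; for H and the remaining
elements derived as photo*(1-K-fluorescence escape) + incoherent *
Klein-Nishina mean energy-transfer fraction (numerically integrated).

The photo/incoh/coh split (used by the Monte Carlo engine for interaction
sampling) is modelled: incoh = KN * binding suppression, coh = parametric,
photo = mu_tot - incoh - coh (clipped >= 0).

Output: inst/extdata/photon_mass_coefficients.csv
columns: element, Z, A, energy_kev, mu_rho, muen_rho, photo, incoh, coh
"""
import numpy as np

NA_B = 0.602214076  # Avogadro x 1e-24 (barn -> cm^2/g conversion helper)
RE2_B = 0.0794098   # classical electron radius squared, barn
MEC2 = 510.99895    # keV


def kn_sigma(e_kev):
    """Klein-Nishina total and energy-transfer cross sections per electron, barn."""
    k = e_kev / MEC2
    mu = np.linspace(-1.0, 1.0, 4001)
    ratio = 1.0 / (1.0 + k * (1.0 - mu))
    dsdo = 0.5 * RE2_B * ratio**2 * (ratio + 1.0 / ratio - (1.0 - mu**2))
    sig = 2.0 * np.pi * np.trapezoid(dsdo, mu)
    sig_tr = 2.0 * np.pi * np.trapezoid(dsdo * (1.0 - ratio), mu)
    return sig, sig_tr


def loglog_interp(x, xs, ys):
    return np.exp(np.interp(np.log(np.atleast_1d(x)), np.log(xs), np.log(ys)))


class Element:
    def __init__(self, sym, Z, A, mu_anchors, muen_anchors=None, edges=None,
                 wk=0.0, ek_kev=None, efluor_kev=None):
        self.sym, self.Z, self.A = sym, Z, A
        self.mu_anchors = sorted(mu_anchors)
        self.muen_anchors = sorted(muen_anchors) if muen_anchors else None
        self.edges = edges or []
        self.wk, self.ek, self.efluor = wk, ek_kev, efluor_kev

    def mu_rho(self, e):
        xs = np.array([a[0] for a in self.mu_anchors])
        ys = np.array([a[1] for a in self.mu_anchors])
        return loglog_interp(e, xs, ys)

    def incoh(self, e):
        e = np.atleast_1d(e).astype(float)
        sig = np.array([kn_sigma(x)[0] for x in e])
        c = 2.2 * self.Z**0.7
        return sig * e**2 / (e**2 + c**2) * NA_B * self.Z / self.A

    def incoh_tr(self, e):
        e = np.atleast_1d(e).astype(float)
        out = []
        for x in e:
            sig, sig_tr = kn_sigma(x)
            c = 2.2 * self.Z**0.7
            out.append(sig_tr * x**2 / (x**2 + c**2) * NA_B * self.Z / self.A)
        return np.array(out)

    def coh(self, e):
        e = np.atleast_1d(e).astype(float)
        sig0 = 0.665 * self.Z**2 / self.A * NA_B     # forward Thomson limit
        e0 = 1.40 * (self.Z / 8.0)**0.42
        return sig0 / (1.0 + (e / e0)**1.6)

    def split(self, e):
        mu = self.mu_rho(e)
        inc = self.incoh(e)
        coh = self.coh(e)
        # keep the split consistent with the anchored total
        sc = np.minimum(inc + coh, 0.999 * mu)
        scale = np.where(inc + coh > 0, sc / np.maximum(inc + coh, 1e-30), 1.0)
        inc, coh = inc * scale, coh * scale
        photo = np.maximum(mu - inc - coh, 1e-9)
        return photo, inc, coh

    def muen_model(self, e):
        e = np.atleast_1d(e).astype(float)
        photo, inc, _ = self.split(e)
        floss = np.zeros_like(e)
        if self.ek is not None and self.wk > 0:
            above = e >= self.ek
            floss[above] = self.wk * self.efluor / e[above]
        ftr = self.incoh_tr(e) / np.maximum(self.incoh(e), 1e-30)
        return photo * (1.0 - floss) + inc * ftr

    def muen_rho(self, e):
        e = np.atleast_1d(e).astype(float)
        if self.muen_anchors is None:
            return self.muen_model(e)
        xs = np.array([a[0] for a in self.muen_anchors])
        ys = np.array([a[1] for a in self.muen_anchors])
        out = np.empty_like(e)
        lo = e < xs[0]
        out[~lo] = loglog_interp(e[~lo], xs, ys) if np.any(~lo) else 0
        if np.any(lo):
            # continue with the physics model below the anchored range,
            # scaled for continuity at the first anchor
            scale = ys[0] / self.muen_model(np.array([xs[0]]))[0]
            out[lo] = self.muen_model(e[lo]) * scale
        return out


MUEN_WATER = [(10, 4.944), (15, 1.374), (20, 0.5503), (30, 0.1557),
              (40, 0.0695), (50, 0.04223), (60, 0.03190), (80, 0.02597),
              (100, 0.02546), (150, 0.02764)]
MUEN_AIR = [(10, 4.742), (15, 1.334), (20, 0.5389), (30, 0.1537),
            (40, 0.06833), (50, 0.04098), (60, 0.03041), (80, 0.02407),
            (100, 0.02325), (150, 0.02496)]

ELEMENTS = [
    Element("H", 1, 1.008, [
        (1, 7.217), (1.5, 2.148), (2, 1.059), (3, 0.5612), (4, 0.4546),
        (5, 0.4193), (6, 0.4042), (8, 0.3914), (10, 0.3854), (15, 0.3764),
        (20, 0.3695), (30, 0.357), (40, 0.3458), (50, 0.3355), (60, 0.3260),
        (80, 0.3091), (100, 0.2944), (150, 0.2651)]),
    Element("C", 6, 12.011, [
        (1, 2211), (1.5, 700.2), (2, 303), (3, 92.0), (4, 36.6), (5, 19.1),
        (6, 10.95), (8, 4.576), (10, 2.373), (15, 0.8071), (20, 0.4420),
        (30, 0.2562), (40, 0.2076), (50, 0.1871), (60, 0.1753), (80, 0.1610),
        (100, 0.1514), (150, 0.1347)],
        muen_anchors=[(10, 2.078), (15, 0.5627), (20, 0.2238), (30, 0.06614),
                      (40, 0.03343), (50, 0.02397), (60, 0.02098),
                      (80, 0.02037), (100, 0.02147), (150, 0.02449)]),
    Element("N", 7, 14.007, [
        (1, 3311), (1.5, 1083), (2, 476), (3, 145), (4, 60.1), (5, 31.3),
        (6, 17.9), (8, 7.56), (10, 3.879), (15, 1.236), (20, 0.6178),
        (30, 0.3066), (40, 0.2288), (50, 0.1980), (60, 0.1817), (80, 0.1639),
        (100, 0.1529), (150, 0.1353)]),
    Element("O", 8, 15.999, [
        (1, 4590), (1.5, 1549), (2, 694), (3, 217), (4, 90.8), (5, 47.9),
        (6, 27.5), (8, 11.63), (10, 5.952), (15, 1.836), (20, 0.8651),
        (30, 0.3779), (40, 0.2585), (50, 0.2132), (60, 0.1907), (80, 0.1678),
        (100, 0.1551), (150, 0.1361)]),
    Element("Na", 11, 22.990, [
        (1, 500), (2, 130), (3, 46), (5, 11.2), (10, 15.6), (15, 4.68),
        (20, 2.10), (30, 0.84), (50, 0.41), (100, 0.170), (150, 0.139)],
        wk=0.023, ek_kev=1.0721, efluor_kev=1.041),
    Element("Mg", 12, 24.305, [
        (1, 750), (2, 1825), (5, 155), (10, 21.1), (30, 1.02), (60, 0.262),
        (100, 0.172), (150, 0.141)], wk=0.030, ek_kev=1.305,
        efluor_kev=1.254),
    Element("Al", 13, 26.982, [
        (1, 1185), (1.5, 402.2), (1.5597, 362.1), (1.5601, 3957), (2, 2263),
        (3, 788), (4, 360.5), (5, 193.4), (6, 115.3), (8, 50.33), (10, 26.23),
        (15, 7.955), (20, 3.441), (30, 1.128), (40, 0.5685), (50, 0.3681),
        (60, 0.2778), (80, 0.2018), (100, 0.1704), (150, 0.1378)],
        muen_anchors=[(10, 25.43), (15, 7.487), (20, 3.094), (30, 0.8778),
                      (40, 0.3601), (50, 0.1840), (60, 0.1099),
                      (80, 0.05511), (100, 0.03794), (150, 0.02827)],
        edges=[1.5599], wk=0.039, ek_kev=1.5599, efluor_kev=1.487),
    Element("P", 15, 30.974, [
        (1, 1800), (2.143, 290), (2.147, 1365), (3, 560), (4, 260), (5, 139),
        (6, 84), (8, 37.8), (10, 40.5), (15, 12.2), (20, 5.2), (30, 1.83),
        (40, 0.94), (50, 0.62), (60, 0.47), (80, 0.30), (100, 0.205),
        (150, 0.154)], edges=[2.1455], wk=0.063, ek_kev=2.1455,
        efluor_kev=2.014),
    Element("S", 16, 32.06, [
        (1, 2000), (2.470, 430), (2.474, 2070), (3, 1155), (4, 520), (5, 280),
        (6, 170), (8, 75), (10, 50.8), (15, 15.2), (20, 6.6), (30, 2.17),
        (40, 1.10), (50, 0.72), (60, 0.53), (80, 0.33), (100, 0.227),
        (150, 0.164)], edges=[2.472], wk=0.078, ek_kev=2.472,
        efluor_kev=2.307),
    Element("Cl", 17, 35.45, [
        (1, 2200), (2.820, 590), (2.824, 2650), (4, 935), (5, 500), (6, 300),
        (8, 132), (10, 58.0), (15, 17.4), (20, 7.5), (30, 2.42), (40, 1.25),
        (50, 0.79), (60, 0.57), (80, 0.35), (100, 0.235), (150, 0.165)],
        edges=[2.822], wk=0.097, ek_kev=2.822, efluor_kev=2.622),
    Element("Ar", 18, 39.948, [
        (1, 3100), (2, 510), (3, 175), (3.201, 143), (3.205, 1950), (4, 1000),
        (5, 516), (6, 302), (8, 128), (10, 62.9), (15, 18.6), (20, 8.0),
        (30, 2.45), (40, 1.30), (50, 0.82), (60, 0.46), (80, 0.30),
        (100, 0.213), (150, 0.157)], edges=[3.203], wk=0.118, ek_kev=3.203,
        efluor_kev=2.957),
    Element("K", 19, 39.098, [
        (1, 4060), (2, 630), (3, 215), (3.605, 131), (3.609, 1640), (4, 1190),
        (5, 640), (6, 378), (8, 160), (10, 78), (15, 23.4), (20, 10.1),
        (30, 3.10), (40, 1.40), (50, 0.95), (60, 0.52), (80, 0.32),
        (100, 0.231), (150, 0.163)], edges=[3.607], wk=0.140, ek_kev=3.607,
        efluor_kev=3.313),
    Element("Ca", 20, 40.078, [
        (1, 3450), (2, 570), (3, 200), (4.036, 145), (4.040, 1230), (6, 390),
        (8, 172), (10, 93.4), (15, 27.9), (20, 12.1), (30, 3.66), (40, 1.65),
        (50, 0.93), (60, 0.61), (80, 0.35), (100, 0.251), (150, 0.168)],
        edges=[4.038], wk=0.163, ek_kev=4.038, efluor_kev=3.690),
    Element("Cu", 29, 63.546, [
        (1, 10570), (1.5, 4418), (2, 2154), (3, 748.8), (4, 347.3), (5, 189.9),
        (6, 117.0), (8, 52.55), (8.977, 38.3), (8.981, 278.4), (10, 215.9),
        (15, 74.05), (20, 33.79), (30, 10.92), (40, 4.862), (50, 2.613),
        (60, 1.593), (80, 0.763), (100, 0.4584), (150, 0.2217)],
        muen_anchors=[(10, 148.4), (15, 57.88), (20, 27.88), (30, 9.349),
                      (40, 4.163), (50, 2.192), (60, 1.290), (80, 0.5581),
                      (100, 0.3148), (150, 0.1172)],
        edges=[8.979], wk=0.440, ek_kev=8.979, efluor_kev=8.041),
    Element("Gd", 64, 157.25, [
        (1, 3900), (2, 840), (3, 280), (4, 125), (5, 69), (6, 42),
        (7.241, 26), (7.245, 62), (7.928, 52), (7.932, 73), (8.374, 68),
        (8.378, 94), (10, 64), (15, 22.2), (20, 10.2), (30, 3.70), (40, 1.79),
        (50.237, 1.05), (50.242, 4.90), (60, 2.98), (80, 1.37), (100, 0.78),
        (150, 0.31)], edges=[7.243, 7.930, 8.376, 50.2399], wk=0.93,
        ek_kev=50.2399, efluor_kev=43.0),
    Element("W", 74, 183.84, [
        (1, 3700), (2, 3800), (3, 2100), (4, 1000), (5, 560), (6, 330),
        (8, 163), (10.204, 90), (10.210, 217), (11.541, 160), (11.547, 224),
        (12.097, 199), (12.103, 231), (15, 135), (20, 65.7), (30, 22.7),
        (40, 10.67), (50, 5.949), (60, 3.713), (69.522, 2.50), (69.528, 11.0),
        (80, 7.81), (100, 4.438), (150, 1.581)],
        edges=[10.207, 11.544, 12.100, 69.525], wk=0.958, ek_kev=69.525,
        efluor_kev=59.3),
]

BY_SYM = {el.sym: el for el in ELEMENTS}

# Solve N and O muen anchors from the NIST air/water compound values.
W_WATER = {"H": 0.111894, "O": 0.888106}
W_AIR = {"C": 0.000124, "N": 0.755267, "O": 0.231781, "Ar": 0.012827}
o_anch, n_anch = [], []
for (e, mw), (_, ma) in zip(MUEN_WATER, MUEN_AIR):
    muen_h = BY_SYM["H"].muen_rho(e)[0]
    muen_o = (mw - W_WATER["H"] * muen_h) / W_WATER["O"]
    o_anch.append((e, muen_o))
BY_SYM["O"].muen_anchors = o_anch
for (e, ma) in MUEN_AIR:
    muen_o = BY_SYM["O"].muen_rho(e)[0]
    muen_ar = BY_SYM["Ar"].muen_rho(e)[0]
    muen_c = BY_SYM["C"].muen_rho(e)[0]
    muen_n = (ma - W_AIR["O"] * muen_o - W_AIR["Ar"] * muen_ar
              - W_AIR["C"] * muen_c) / W_AIR["N"]
    n_anch.append((e, muen_n))
BY_SYM["N"].muen_anchors = n_anch

GRID = [1, 1.5, 2, 3, 4, 5, 6, 8, 10, 12, 15, 20, 25, 30, 35, 40, 45, 50,
        55, 60, 65, 70, 80, 90, 100, 110, 120, 130, 140, 150]


def main():
    rows = []
    for el in ELEMENTS:
        eg = list(GRID)
        for edge in el.edges:
            eg += [edge - 0.002, edge + 0.002]
        eg = np.array(sorted(set(eg)))
        mu = el.mu_rho(eg)
        muen = el.muen_rho(eg)
        ph, inc, coh = el.split(eg)
        for i, e in enumerate(eg):
            rows.append((el.sym, el.Z, el.A, e, mu[i], muen[i], ph[i],
                         inc[i], coh[i]))
    with open("inst/extdata/photon_mass_coefficients.csv", "w") as fh:
        fh.write("element,Z,A,energy_kev,mu_rho,muen_rho,photo,incoh,coh\n")
        for r in rows:
            fh.write("%s,%d,%.4f,%.4f,%.6g,%.6g,%.6g,%.6g,%.6g\n" % r)
    print("rows:", len(rows))

    def mix(fracs, e, kind):
        tot = 0.0
        for sym, w in fracs.items():
            el = BY_SYM[sym]
            tot += w * (el.mu_rho(e) if kind == "mu" else el.muen_rho(e))[0]
        return tot

    checks = [
        ("water mu 10", W_WATER, "mu", 10, 5.329),
        ("water mu 30", W_WATER, "mu", 30, 0.3756),
        ("water mu 50", W_WATER, "mu", 50, 0.2269),
        ("water mu 100", W_WATER, "mu", 100, 0.1707),
        ("water muen 30", W_WATER, "muen", 30, 0.1557),
        ("water muen 60", W_WATER, "muen", 60, 0.03190),
        ("water muen 100", W_WATER, "muen", 100, 0.02546),
        ("air mu 30", W_AIR, "mu", 30, 0.3538),
        ("air mu 60", W_AIR, "mu", 60, 0.1875),
        ("air mu 100", W_AIR, "mu", 100, 0.1541),
        ("air muen 20", W_AIR, "muen", 20, 0.5389),
        ("air muen 40", W_AIR, "muen", 40, 0.06833),
        ("air muen 60", W_AIR, "muen", 60, 0.03041),
        ("air muen 80", W_AIR, "muen", 80, 0.02407),
        ("air muen 100", W_AIR, "muen", 100, 0.02325),
        ("H muen 100 (KN)", {"H": 1.0}, "muen", 100, 0.04063),
        ("H muen 60 (KN)", {"H": 1.0}, "muen", 60, 0.03053),
    ]
    print("%-18s %10s %10s %8s" % ("check", "model", "ref", "err%"))
    for name, fr, kind, e, ref in checks:
        v = mix(fr, e, kind)
        print("%-18s %10.4g %10.4g %7.2f%%" % (name, v, ref, 100*(v/ref-1)))


if __name__ == "__main__":
    main()
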