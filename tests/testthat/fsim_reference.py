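# Independent NumPy reference implementation of the Feature Similarity
# Index (FSIM) for grayscale images, following the published algorithm:
# phase congruency from a log-Gabor filter bank (4 scales, 4 orientations,
# minimum wavelength 6, multiplier 2, sigmaOnf 0.55) with noise-energy
# compensation, Scharr gradient magnitudes, and phase-congruency-weighted
# pooling of the combined per-pixel similarity. Inputs are text matrices on
# the 0-255 scale. Used only as a cross-check oracle by the test suite.
import sys
import numpy as np


def lowpass(rows, cols):
    xr = (np.arange(-(cols - 1) / 2, (cols - 1) / 2 + 1) / (cols - 1)
          if cols % 2 else np.arange(-cols / 2, cols / 2) / cols)
    yr = (np.arange(-(rows - 1) / 2, (rows - 1) / 2 + 1) / (rows - 1)
          if rows % 2 else np.arange(-rows / 2, rows / 2) / rows)
    x, y = np.meshgrid(xr, yr)
    radius = np.fft.ifftshift(np.sqrt(x ** 2 + y ** 2))
    theta = np.fft.ifftshift(np.arctan2(-y, x))
    radius[0, 0] = 1.0
    lp = 1.0 / (1.0 + (radius / 0.45) ** 30)
    return radius, theta, lp


def phasecong(im, nscale=4, norient=4, min_wl=6, mult=2.0, sigma_onf=0.55,
              d_theta_sigma=1.2, k=2.0, eps=1e-4):
    rows, cols = im.shape
    radius, theta, lp = lowpass(rows, cols)
    sintheta, costheta = np.sin(theta), np.cos(theta)
    gabor = []
    for s in range(nscale):
        fo = 1.0 / (min_wl * mult ** s)
        g = np.exp(-(np.log(radius / fo)) ** 2 /
                   (2 * np.log(sigma_onf) ** 2)) * lp
        g[0, 0] = 0.0
        gabor.append(g)
    imfft = np.fft.fft2(im)
    theta_sigma = np.pi / norient / d_theta_sigma
    energy_all = np.zeros(im.shape)
    an_all = np.zeros(im.shape)
    for o in range(norient):
        angl = o * np.pi / norient
        ds = sintheta * np.cos(angl) - costheta * np.sin(angl)
        dc = costheta * np.cos(angl) + sintheta * np.sin(angl)
        spread = np.exp(-np.arctan2(ds, dc) ** 2 / (2 * theta_sigma ** 2))
        eo = [np.fft.ifft2(imfft * gabor[s] * spread) for s in range(nscale)]
        an = [np.abs(e) for e in eo]
        sum_an = np.sum(an, axis=0)
        sum_e = np.sum([e.real for e in eo], axis=0)
        sum_o = np.sum([e.imag for e in eo], axis=0)
        tau = np.median(an[0]) / np.sqrt(np.log(4))
        x_energy = np.sqrt(sum_e ** 2 + sum_o ** 2) + eps
        mean_e, mean_o = sum_e / x_energy, sum_o / x_energy
        energy = np.zeros(im.shape)
        for s in range(nscale):
            e, od = eo[s].real, eo[s].imag
            energy += e * mean_e + od * mean_o - np.abs(e * mean_o - od * mean_e)
        total_tau = tau * (1 - (1 / mult) ** nscale) / (1 - 1 / mult)
        T = (total_tau * np.sqrt(np.pi / 2) +
             k * total_tau * np.sqrt((4 - np.pi) / 2)) / 1.7
        energy_all += np.maximum(energy - T, 0.0)
        an_all += sum_an
    return energy_all / (an_all + eps)


def scharr_mag(im):
    dx = np.array([[3, 0, -3], [10, 0, -10], [3, 0, -3]], float) / 16.0
    pad = np.pad(im, 1)
    gx = np.zeros_like(im)
    gy = np.zeros_like(im)
    n, m = im.shape
    for i in range(3):
        for j in range(3):
            if dx[i, j]:
                gx += dx[i, j] * pad[i:i + n, j:j + m]
            if dx.T[i, j]:
                gy += dx.T[i, j] * pad[i:i + n, j:j + m]
    return np.sqrt(gx ** 2 + gy ** 2)


def fsim(a, b, t1=0.85, t2=160.0):
    pc1, pc2 = phasecong(a), phasecong(b)
    g1, g2 = scharr_mag(a), scharr_mag(b)
    s_pc = (2 * pc1 * pc2 + t1) / (pc1 ** 2 + pc2 ** 2 + t1)
    s_g = (2 * g1 * g2 + t2) / (g1 ** 2 + g2 ** 2 + t2)
    pcm = np.maximum(pc1, pc2)
    return float(np.sum(s_pc * s_g * pcm) / np.sum(pcm))


if __name__ == "__main__":
    # args: pairs.txt (lines: fileA fileB), each file a whitespace matrix
    with open(sys.argv[1]) as fh:
        for line in fh:
            fa, fb = line.split()
            a = np.loadtxt(fa)
            b = np.loadtxt(fb)
            print(repr(fsim(a, b)))
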