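type,n,area_median,area_mad,length_median,length_mad,diameter_median,diameter_mad
cp,119,1.9,1.0,3.2,1.1,0.6,0.2
cv,39,4.2,2.0,6.0,2.5,0.8,0.3
ca,80,2.6,1.2,5.9,2.0,0.5,0.2
cx,4,0.9,0.5,3.1,2.0,0.3,0.1
cy,1,1.9,NA,3.5,NA,0.6,NA
pa,174,2.0,1.2,4.4,1.7,0.5,0.2
px,92,1.1,0.8,2.6,1.1,0.4,0.2
py,6,1.3,0.7,3.6,0.6,0.5,0.1
xa,102,1.4,0.7,2.9,1.1,0.5,0.2
xy,18,0.9,0.7,2.3,1.0,0.4,0.1
ya,15,1.1,0.9,1.9,1.3,0.6,0.3
pv,6,4.3,0.8,6.2,0.5,0.7,0.1
xv,2,2.8,NA,5.3,NA,0.5,NA
yv,0,NA,NA,NA,NA,NA,NA
av,174,2.9,1.6,3.2,1.1,0.9,0.3
ii,24,1.0,0.8,2.4,1.1,0.4,0.2
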