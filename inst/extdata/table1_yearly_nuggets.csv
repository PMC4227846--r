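region,family,year,nugget
northeast,gompertz,2008,0.8603
northeast,gompertz,2009,0.6606
northeast,gompertz,2010,0.6604
northeast,gompertz,2011,0.6604
northeast,gompertz,2012,NA
northeast,negexp,2008,NA
northeast,negexp,2009,0.6603
northeast,negexp,2010,0.6604
northeast,negexp,2011,0.6604
northeast,negexp,2012,NA
centre,gompertz,2008,0.4430
centre,gompertz,2009,0.5390
centre,gompertz,2010,0.5543
centre,gompertz,2011,0.2573
centre,gompertz,2012,0.4474
centre,negexp,2008,0.4424
centre,negexp,2009,0.5376
centre,negexp,2010,0.5547
centre,negexp,2011,0.1950
centre,negexp,2012,0.4463
southwest,gompertz,2008,0.4369
southwest,gompertz,2009,NA
southwest,gompertz,2010,0.3486
southwest,gompertz,2011,NA
southwest,gompertz,2012,0.6261
southwest,negexp,2008,0.4365
southwest,negexp,2009,NA
southwest,negexp,2010,0.3351
southwest,negexp,2011,0.1300
southwest,negexp,2012,0.6261
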