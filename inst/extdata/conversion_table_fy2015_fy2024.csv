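"base_points","More than 2,000,000","1,000,000 to 2,000,000","500,000 to 1,000,000","300,000 to 500,000","100,000 to 300,000","50,000 to 100,000","30,000 to 50,000","10,000 to 30,000","5000 to 10,000","3000 to 5000","1000 to 3000","500 to 1000","100 to 500","10 to 100","1 to 10"
"50","104","260","260","273","585","1,287","1,560","6,500","10,920","11,050","31,070","37,310","70,070","66,560","183,430"
"45","96","240","240","252","540","1,188","1,440","6,000","10,080","10,200","28,680","34,440","64,680","61,440","169,320"
"40","88","220","220","231","495","1,089","1,320","5,500","9,240","9,350","26,290","31,570","59,290","56,320","155,210"
"35","80","200","200","210","450","990","1,200","5,000","8,400","8,500","23,900","28,700","53,900","51,200","141,100"
"30","72","180","180","189","405","891","1,080","4,500","7,560","7,650","21,510","25,830","48,510","46,080","126,990"
"25","64","160","160","168","360","792","960","4,000","6,720","6,800","19,120","22,960","43,120","40,960","112,880"
"20","56","140","140","147","315","693","840","3,500","5,880","5,950","16,730","20,090","37,730","35,840","98,770"
"15","48","120","120","126","270","594","720","3,000","5,040","5,100","14,340","17,220","32,340","30,720","84,660"
"10","40","100","100","105","225","495","600","2,500","4,200","4,250","11,950","14,350","26,950","25,600","70,550"
"5","32","80","80","84","180","396","480","2,000","3,360","3,400","9,560","11,480","21,560","20,480","56,440"
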